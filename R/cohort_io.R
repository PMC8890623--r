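# Parsing of COSMIC-mutant-export-style mutation tables into per-record and
# per-sample structures, with the cohort-level sample filters.

#' Default column map for a COSMIC mutant-export-style table
#'
#' Maps the package's record fields to header names in the input TSV. The
#' genomic position may come either from a single \code{position} column in
#' \code{"chrom:start-end"} form (the COSMIC dialect) or from separate
#' \code{chrom}, \code{start} and \code{end} columns; set the unused
#' alternative to \code{NA}.
#'
#' @param ... named overrides, e.g. \code{sample_id = "ID_sample"}.
#' @return named list of column names.
#' @export
cosmic_columns <- function(...) {
  map <- list(sample_id = "ID_sample", sample_code = "Sample name",
              tumor_type = "Primary site", gene = "Gene name",
              aa_change = "Mutation AA",
              position = "Mutation genome position",
              chrom = NA_character_, start = NA_character_,
              end = NA_character_,
              mutation_class = "Mutation Description",
              genome_screen = "Genome-wide screen")
  dots <- list(...)
  bad <- setdiff(names(dots), names(map))
  if (length(bad)) stop("unknown column-map fields: ", paste(bad, collapse = ", "))
  map[names(dots)] <- dots
  map
}

# Collapse a free-text mutation description to a coarse class.
mutation_class_of <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  out[grepl("substitution", x)] <- "substitution"
  out[grepl("insertion", x)] <- "insertion"
  out[grepl("deletion", x)] <- "deletion"
  out
}

#' Read a mutation export table
#'
#' Reads a tab-separated mutation table (COSMIC mutant-export dialect by
#' default), keeps only rows flagged as genome-wide screens
#' (\code{genome_screen == "y"}), drops rows whose genomic coordinates cannot
#' be parsed (reporting the count), and optionally collapses duplicate
#' identical mutation rows within a sample. Row order is preserved.
#'
#' @param path TSV file with a header row.
#' @param columns column map from [cosmic_columns()].
#' @param genome_screen_only keep only \code{genome_screen == "y"} rows
#'   (default TRUE).
#' @param dedup_rows count duplicate identical rows (same sample, coordinates
#'   and protein change) once (default TRUE).
#' @return data.frame of mutation records: \code{sample_id},
#'   \code{sample_code}, \code{tumor_type}, \code{gene}, \code{aa_change},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive, as exported),
#'   \code{mutation_class}, \code{genome_screen}.
#' @export
read_mutation_export <- function(path, columns = cosmic_columns(),
                                 genome_screen_only = TRUE,
                                 dedup_rows = TRUE) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL)
  if (!nrow(raw)) stop("mutation table is empty: ", path)

  need <- c("sample_id", "sample_code", "tumor_type", "gene", "aa_change",
            "mutation_class", "genome_screen")
  use_pos <- !is.na(columns$position)
  need <- c(need, if (use_pos) "position" else c("chrom", "start", "end"))
  missing <- vapply(need, function(f) !(columns[[f]] %in% names(raw)), TRUE)
  if (any(missing))
    stop("required columns missing from ", path, ": ",
         paste(unlist(columns[need[missing]]), collapse = ", "))

  col <- function(f) raw[[columns[[f]]]]
  rec <- data.frame(sample_id = col("sample_id"),
                    sample_code = col("sample_code"),
                    tumor_type = col("tumor_type"),
                    gene = col("gene"),
                    aa_change = col("aa_change"),
                    mutation_class = mutation_class_of(col("mutation_class")),
                    genome_screen = tolower(col("genome_screen")),
                    stringsAsFactors = FALSE)
  if (use_pos) {
    pos <- col("position")
    ok <- grepl("^[^:]+:[0-9]+-[0-9]+$", pos)
    rec$chrom <- sub(":.*$", "", pos)
    rec$start <- suppressWarnings(as.integer(sub("^[^:]+:([0-9]+)-.*$", "\\1", pos)))
    rec$end <- suppressWarnings(as.integer(sub("^.*-([0-9]+)$", "\\1", pos)))
    rec$chrom[!ok] <- NA_character_
  } else {
    rec$chrom <- col("chrom")
    rec$start <- suppressWarnings(as.integer(col("start")))
    rec$end <- suppressWarnings(as.integer(col("end")))
  }

  bad <- is.na(rec$chrom) | is.na(rec$start) | is.na(rec$end)
  if (any(bad)) {
    message("read_mutation_export: dropped ", sum(bad),
            " row(s) with unparseable genomic coordinates")
    rec <- rec[!bad, , drop = FALSE]
  }
  if (genome_screen_only) rec <- rec[rec$genome_screen == "y", , drop = FALSE]
  if (dedup_rows) {
    key <- rec[c("sample_id", "chrom", "start", "end", "aa_change", "gene")]
    dup <- duplicated(key)
    if (any(dup)) {
      message("read_mutation_export: collapsed ", sum(dup),
              " duplicate identical row(s)")
      rec <- rec[!dup, , drop = FALSE]
    }
  }
  rec <- rec[c("sample_id", "sample_code", "tumor_type", "gene", "aa_change",
               "chrom", "start", "end", "mutation_class", "genome_screen")]
  rownames(rec) <- NULL
  rec
}

#' Remove samples whose code is tied to more than one tumor type
#'
#' A sample code associated with more than one tumor type in the export is
#' ambiguous; every record of such samples is removed.
#'
#' @param records mutation-record data.frame.
#' @return filtered records.
#' @export
dedupe_samples <- function(records) {
  if (!nrow(records)) return(records)
  tt <- tapply(records$tumor_type, records$sample_code,
               function(x) length(unique(x)))
  bad <- names(tt)[tt > 1L]
  if (length(bad))
    message("dedupe_samples: removed ", length(bad),
            " sample code(s) assigned to multiple tumor types")
  out <- records[!(records$sample_code %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample mutation totals
#'
#' Aggregates deduplicated records into one profile per sample with its total
#' mutation count. The TOP1 domain group starts as \code{"none"} and the
#' percent-at-G4 as \code{NA} until assigned downstream.
#'
#' @param records mutation-record data.frame (after [dedupe_samples()]).
#' @return data.frame of sample profiles: \code{sample_id},
#'   \code{sample_code}, \code{tumor_type}, \code{total_mutations},
#'   \code{top1_group}, \code{pct_at_g4}.
#' @export
per_sample_totals <- function(records) {
  if (!nrow(records))
    return(data.frame(sample_id = character(), sample_code = character(),
                      tumor_type = character(), total_mutations = integer(),
                      top1_group = character(), pct_at_g4 = double(),
                      stringsAsFactors = FALSE))
  first <- !duplicated(records$sample_id)
  counts <- table(records$sample_id)
  prof <- data.frame(sample_id = records$sample_id[first],
                     sample_code = records$sample_code[first],
                     tumor_type = records$tumor_type[first],
                     stringsAsFactors = FALSE)
  prof$total_mutations <- as.integer(counts[prof$sample_id])
  prof$top1_group <- "none"
  prof$pct_at_g4 <- NA_real_
  prof <- prof[order(prof$sample_id), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}
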