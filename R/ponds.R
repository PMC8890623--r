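# Genome-level PONDS annotation: per-chromosome scanning of both strands and
# merging of overlapping motif hits into maximal PONDS intervals (BED).

# Convert a motif/BED-like data.frame (0-based half-open) to GRanges.
bed_to_granges <- function(bed) {
  if (!nrow(bed)) return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(bed)) bed$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(bed$chrom,
                         IRanges::IRanges(start = bed$start + 1L, end = bed$end),
                         strand = strand)
}

#' Scan a FASTA (or DNAStringSet) for PONDS intervals
#'
#' Scans every chromosome on both strands in either canonical or QGRS mode and
#' merges overlapping motif hits from either strand into maximal potential
#' non-B DNA-forming sequence (PONDS) intervals, the annotation track that
#' mutation coordinates are intersected with.
#'
#' Canonical mode scans long chromosomes sequentially in chunks of roughly
#' \code{window} nt, cut only inside non-G stretches longer than the loop
#' bound on the scanned strand (which no motif or greedy match chain can
#' cross), so chunked output is identical to a whole-chromosome scan. QGRS
#' mode is
#' exhaustive enumeration plus best-motif selection per strand and is
#' restricted to sequences of at most 10 kb unless \code{force = TRUE}.
#'
#' @param fasta path to a (multi-)FASTA file, or a
#'   \link[Biostrings]{DNAStringSet}.
#' @param mode \code{"canonical"} or \code{"qgrs"}.
#' @param min_run,loop_min,loop_max canonical-mode parameters (defaults 3, 1, 7).
#' @param max_length,min_group,qgrs_loop_min,qgrs_loop_max QGRS-mode
#'   parameters (defaults 44, 3, 0, 10).
#' @param both_strands scan the reverse strand as well (default TRUE).
#' @param window canonical-mode chunk size in nt (minimum 2000).
#' @param force allow QGRS mode on sequences longer than 10 kb.
#' @param out optional path; when given, the merged intervals are written as
#'   6-column BED (name = motif source, score = best G-score or 0, strand
#'   as merged).
#' @return data.frame of disjoint PONDS intervals sorted by (chrom, start):
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open), \code{name},
#'   \code{score}, \code{strand} (\code{"."} when motifs from both strands
#'   merged).
#' @export
ponds_scan <- function(fasta, mode = c("canonical", "qgrs"),
                       min_run = 3L, loop_min = 1L, loop_max = 7L,
                       max_length = 44L, min_group = 3L,
                       qgrs_loop_min = 0L, qgrs_loop_max = 10L,
                       both_strands = TRUE, window = 500000L,
                       force = FALSE, out = NULL) {
  mode <- match.arg(mode)
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else {
            if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
            Biostrings::readDNAStringSet(fasta)
          }
  nm <- sub("\\s.*$", "", names(seqs))
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all FASTA records must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome names in FASTA")
  names(seqs) <- nm

  hits <- lapply(seq_along(seqs), function(i) {
    s <- toupper(as.character(seqs[[i]]))
    if (mode == "canonical") {
      scan_canonical_windowed(s, nm[i], min_run, loop_min, loop_max,
                              both_strands, window)
    } else {
      fw <- select_best_qgrs(
        enumerate_qgrs(s, max_length, min_group, qgrs_loop_min, qgrs_loop_max,
                       force = force),
        seq = s, max_length = max_length, seqname = nm[i], strand = "+")
      res <- fw
      if (isTRUE(both_strands)) {
        rc <- revcomp_chr(s)
        rv <- select_best_qgrs(
          enumerate_qgrs(rc, max_length, min_group, qgrs_loop_min,
                         qgrs_loop_max, force = force),
          seq = rc, max_length = max_length, seqname = nm[i], strand = "-")
        if (nrow(rv)) {
          L <- nchar(s)
          tmp <- rv$start
          rv$start <- L - rv$end
          rv$end <- L - tmp
          res <- rbind(res, rv)
        }
      }
      res
    }
  })
  motifs <- do.call(rbind, hits)
  bed <- merge_motifs(motifs, mode)
  if (!is.null(out)) write_bed(bed, out)
  bed
}

# Windowed canonical scan of one chromosome. Each strand is cut into chunks
# of roughly `window` nt at positions inside non-G stretches longer than
# loop_max (no motif, and no greedy match chain, can cross such a stretch),
# so chunked scanning is exactly equivalent to scanning the whole string.
scan_canonical_windowed <- function(s, seqname, min_run, loop_min, loop_max,
                                    both_strands, window) {
  window <- max(as.integer(window), 2000L)
  fw <- windowed_strand_scan(s, min_run, loop_min, loop_max, window)
  out <- list()
  if (nrow(fw))
    out$fw <- data.frame(chrom = seqname, start = fw$start, end = fw$end,
                         strand = "+",
                         seq = substring(s, fw$start + 1L, fw$end),
                         g_score = NA_integer_, source = "canonical",
                         stringsAsFactors = FALSE)
  if (isTRUE(both_strands)) {
    rc <- revcomp_chr(s)
    rv <- windowed_strand_scan(rc, min_run, loop_min, loop_max, window)
    if (nrow(rv)) {
      L <- nchar(s)
      out$rv <- data.frame(chrom = seqname,
                           start = L - rv$end, end = L - rv$start,
                           strand = "-",
                           seq = substring(rc, rv$start + 1L, rv$end),
                           g_score = NA_integer_, source = "canonical",
                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_motifs())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Scan one strand in chunks split at safe cut points (middles of non-G
# stretches longer than loop_max). Returns 0-based half-open intervals.
windowed_strand_scan <- function(s, min_run, loop_min, loop_max, window) {
  L <- nchar(s)
  if (L <= window)
    return(scan_one_strand(s, min_run, loop_min, loop_max))
  safe <- gregexpr(sprintf("[^G]{%d,}", loop_max + 1L), s)[[1]]
  cuts <- integer()
  if (safe[1] != -1L) {
    mids <- as.integer(safe) + as.integer(attr(safe, "match.length")) %/% 2L
    target <- window
    for (m in mids) {
      if (m >= target) { cuts <- c(cuts, m); target <- m + window }
    }
  }
  bounds <- c(1L, cuts, L + 1L)  # chunk i is [bounds[i], bounds[i+1]) 1-based
  pieces <- lapply(seq_len(length(bounds) - 1L), function(i) {
    h <- scan_one_strand(substring(s, bounds[i], bounds[i + 1L] - 1L),
                         min_run, loop_min, loop_max)
    if (nrow(h)) { h$start <- h$start + bounds[i] - 1L
                   h$end <- h$end + bounds[i] - 1L }
    h
  })
  do.call(rbind, pieces)
}

# Merge motif hits from either strand into disjoint PONDS intervals.
merge_motifs <- function(motifs, source_label) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (is.null(motifs) || !nrow(motifs)) return(empty)
  gr <- bed_to_granges(motifs)
  GenomicRanges::strand(gr) <- "*"
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(red, gr)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  score <- integer(length(red))
  strand_out <- character(length(red))
  gs <- motifs$g_score
  for (i in seq_along(red)) {
    members <- sh[qh == i]
    sc <- gs[members]
    score[i] <- if (all(is.na(sc))) 0L else max(sc, na.rm = TRUE)
    st <- unique(motifs$strand[members])
    strand_out[i] <- if (length(st) == 1L) st else "."
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1L,
                    end = GenomicRanges::end(red),
                    name = source_label, score = score, strand = strand_out,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write intervals as 6-column BED
#'
#' @param bed data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{name}, \code{score}, \code{strand}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_bed <- function(bed, path) {
  gr <- bed_to_granges(bed)
  if (length(gr)) {
    names(gr) <- if ("name" %in% names(bed)) bed$name else "."
    S4Vectors::mcols(gr)$score <-
      if ("score" %in% names(bed)) as.numeric(bed$score) else 0
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into the package's interval data.frame
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  nm <- if (!is.null(S4Vectors::mcols(gr)$name)) S4Vectors::mcols(gr)$name
        else rep(".", length(gr))
  sc <- if (!is.null(S4Vectors::mcols(gr)$score)) S4Vectors::mcols(gr)$score
        else rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = nm, score = sc, strand = strand, stringsAsFactors = FALSE)
}
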