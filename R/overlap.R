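# Intersection of mutation coordinates with PONDS intervals and per-sample
# percent-of-mutations-at-G4.

#' Build a queryable PONDS interval index
#'
#' Overlapping input intervals are merged on load, so the index always holds
#' disjoint, sorted, strand-blind intervals per chromosome.
#'
#' @param bed PONDS intervals: a data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) — e.g. from [ponds_scan()] or
#'   [read_bed()] — or a path to a BED file.
#' @return a \code{ponds_index} object (reduced
#'   \link[GenomicRanges]{GRanges}).
#' @export
build_ponds_index <- function(bed) {
  if (is.character(bed) && length(bed) == 1L) bed <- read_bed(bed)
  if (!is.data.frame(bed) || !all(c("chrom", "start", "end") %in% names(bed)))
    stop("`bed` must be a BED path or a data.frame with chrom/start/end")
  if (nrow(bed) && any(bed$start < 0 | bed$end <= bed$start))
    stop("malformed BED intervals (need 0 <= start < end); first bad line: ",
         which(bed$start < 0 | bed$end <= bed$start)[1])
  gr <- bed_to_granges(bed)
  GenomicRanges::strand(gr) <- "*"
  structure(list(ranges = GenomicRanges::reduce(gr)), class = "ponds_index")
}

#' @export
print.ponds_index <- function(x, ...) {
  cat("<ponds_index> ", length(x$ranges), " disjoint intervals, ",
      sum(GenomicRanges::width(x$ranges)), " bp on ",
      length(unique(GenomicRanges::seqnames(x$ranges))), " sequence(s)\n",
      sep = "")
  invisible(x)
}

# Mutation records (1-based inclusive COSMIC dialect) to 0-based half-open
# GRanges-ready intervals. Substitutions/deletions span [start-1, end);
# the insertion dialect start = end + 1 becomes the 2-bp flanking interval.
mutation_intervals <- function(records) {
  s0 <- records$start - 1L
  e0 <- records$end
  ins <- records$start == records$end + 1L
  s0[ins] <- records$start[ins] - 2L
  e0[ins] <- records$start[ins]
  data.frame(chrom = records$chrom, start = pmax(s0, 0L), end = e0)
}

#' Does each mutation overlap a PONDS interval?
#'
#' @param records mutation-record data.frame (1-based inclusive coordinates).
#' @param index a \code{ponds_index} from [build_ponds_index()].
#' @return logical vector, one entry per record. Records on chromosomes
#'   absent from the index are \code{FALSE} (reported once per chromosome).
#' @export
mutation_overlaps <- function(records, index) {
  stopifnot(inherits(index, "ponds_index"))
  if (!nrow(records)) return(logical())
  iv <- mutation_intervals(records)
  known <- as.character(unique(GenomicRanges::seqnames(index$ranges)))
  miss <- setdiff(unique(iv$chrom), known)
  if (length(miss) && length(known))
    message("mutation_overlaps: ", length(miss),
            " chromosome(s) absent from the PONDS index: ",
            paste(utils::head(miss, 5), collapse = ", "))
  out <- rep(FALSE, nrow(iv))
  ok <- iv$chrom %in% known
  if (any(ok)) {
    gr <- GenomicRanges::GRanges(iv$chrom[ok],
                                 IRanges::IRanges(start = iv$start[ok] + 1L,
                                                  end = iv$end[ok]))
    out[ok] <- GenomicRanges::countOverlaps(gr, index$ranges,
                                            ignore.strand = TRUE) > 0L
  }
  out
}

#' Percent of each sample's mutations at G4 PONDS
#'
#' Per-mutation counting: each record counts once regardless of span, and the
#' per-sample value is 100 * (overlapping records) / (total records).
#'
#' @param records mutation-record data.frame.
#' @param index a \code{ponds_index}.
#' @return data.frame with \code{sample_id}, \code{total}, \code{n_at_g4} and
#'   \code{pct_at_g4}, sorted by sample id.
#' @export
pct_at_g4 <- function(records, index) {
  if (!nrow(records))
    return(data.frame(sample_id = character(), total = integer(),
                      n_at_g4 = integer(), pct_at_g4 = double()))
  hit <- mutation_overlaps(records, index)
  total <- table(records$sample_id)
  nhit <- tapply(hit, records$sample_id, sum)
  ids <- sort(names(total))
  data.frame(sample_id = ids,
             total = as.integer(total[ids]),
             n_at_g4 = as.integer(nhit[ids]),
             pct_at_g4 = 100 * as.integer(nhit[ids]) / as.integer(total[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Attach percent-at-G4 values to sample profiles
#'
#' @param profiles sample profiles.
#' @param records mutation records.
#' @param index a \code{ponds_index}.
#' @return \code{profiles} with \code{pct_at_g4} filled in (NA for samples
#'   without records).
#' @export
add_pct_at_g4 <- function(profiles, records, index) {
  pct <- pct_at_g4(records, index)
  m <- match(profiles$sample_id, pct$sample_id)
  profiles$pct_at_g4 <- pct$pct_at_g4[m]
  profiles
}
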