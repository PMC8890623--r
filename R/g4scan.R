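# G-quadruplex motif detection: canonical pattern scan, QGRS-style
# enumeration with integer G-scoring, and genome-level PONDS interval export.
#
# Coordinates are 0-based half-open throughout this module (BED convention);
# reverse-strand hits are reported in forward-genome coordinates.

#' Find maximal guanine runs in a DNA sequence
#'
#' @param seq single DNA string over \{A,C,G,T,N\} (case-insensitive). N never
#'   counts as G.
#' @param min_len minimum run length to report (>= 1).
#' @return data.frame with columns \code{offset} (0-based) and \code{length},
#'   in ascending offset order. Each reported run is maximal.
#' @examples
#' find_g_runs("GAGGGT", 3)  # one run at offset 2, length 3
#' @export
find_g_runs <- function(seq, min_len = 3L) {
  s <- check_dna(seq)
  if (!is.numeric(min_len) || min_len < 1) stop("`min_len` must be >= 1")
  m <- gregexpr(sprintf("G{%d,}", as.integer(min_len)), s)[[1]]
  if (m[1] == -1L)
    return(data.frame(offset = integer(), length = integer()))
  data.frame(offset = as.integer(m) - 1L,
             length = as.integer(attr(m, "match.length")))
}

# Scan one strand (a character string already upper-cased) for the canonical
# pattern; returns 0-based half-open intervals on that string.
scan_one_strand <- function(s, min_run, loop_min, loop_max) {
  pat <- sprintf("G{%d,}([ACGTN]{%d,%d}G{%d,}){3}",
                 min_run, loop_min, loop_max, min_run)
  m <- gregexpr(pat, s, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  st <- as.integer(m) - 1L
  data.frame(start = st, end = st + as.integer(attr(m, "match.length")))
}

#' Scan a sequence for canonical G4 motifs
#'
#' Matches the minimal quadruplex-capable pattern
#' \code{G{min_run,}(N{loop_min,loop_max}G{min_run,}){3}} with standard greedy,
#' leftmost, non-overlapping regular-expression semantics. Loops may contain
#' any base (including G and N); N never extends a guanine run.
#'
#' @param seq single DNA string.
#' @param min_run minimum guanine-run length (default 3).
#' @param loop_min,loop_max loop-length bounds in nt (defaults 1 and 7, the
#'   canonical \code{GGGN1-7} definition).
#' @param both_strands also scan the reverse complement and report those hits
#'   in forward coordinates with strand \code{"-"} (default TRUE).
#' @param seqname chromosome/sequence name used in the output (default "seq").
#' @return data.frame of motifs: \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open, forward coordinates), \code{strand}, \code{seq} (the
#'   matched sequence on the G-rich strand), \code{g_score} (NA for canonical
#'   hits), \code{source = "canonical"}; sorted by (start, strand).
#' @examples
#' smug <- "GAGCTGGGGTGAGCTGGGCTGAGCTGGGGTGAGCTGGGCTGAGCT"
#' scan_canonical(smug)
#' @export
scan_canonical <- function(seq, min_run = 3L, loop_min = 1L, loop_max = 7L,
                           both_strands = TRUE, seqname = "seq") {
  s <- check_dna(seq)
  min_run <- as.integer(min_run); loop_min <- as.integer(loop_min)
  loop_max <- as.integer(loop_max)
  if (min_run < 2) stop("`min_run` must be >= 2")
  if (loop_min < 0 || loop_max < loop_min) stop("invalid loop bounds")
  if (nchar(s) == 0) return(empty_motifs())

  fw <- scan_one_strand(s, min_run, loop_min, loop_max)
  out <- list()
  if (nrow(fw))
    out$fw <- data.frame(chrom = seqname, start = fw$start, end = fw$end,
                         strand = "+",
                         seq = substring(s, fw$start + 1L, fw$end),
                         g_score = NA_integer_, source = "canonical",
                         stringsAsFactors = FALSE)
  if (isTRUE(both_strands)) {
    rc <- revcomp_chr(s)
    rv <- scan_one_strand(rc, min_run, loop_min, loop_max)
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

#' Enumerate QGRS candidates in a sequence
#'
#' A QGRS candidate is four equal-size guanine groups (each a contiguous
#' sub-run of a maximal G run) of size \code{g >= min_group}, separated by
#' three loops with lengths in \code{[loop_min, loop_max]}, with total length
#' \code{4*g + l1 + l2 + l3 <= max_length}. Enumeration is exhaustive and is
#' intended for oligo-scale sequences (guarded at 10 kb unless
#' \code{force = TRUE}).
#'
#' @param seq single DNA string.
#' @param max_length maximum candidate span in nt (default 44).
#' @param min_group minimum guanine-group size (default 3).
#' @param loop_min,loop_max loop-length bounds (defaults 0 and 10).
#' @param force allow sequences longer than 10 kb.
#' @return data.frame of candidates with 0-based group offsets \code{s1..s4},
#'   group size \code{g}, loop lengths \code{l1,l2,l3}, \code{start},
#'   \code{end} (half-open span) and \code{length}; deduplicated by
#'   (offsets, g).
#' @export
enumerate_qgrs <- function(seq, max_length = 44L, min_group = 3L,
                           loop_min = 0L, loop_max = 10L, force = FALSE) {
  s <- check_dna(seq)
  max_length <- as.integer(max_length); min_group <- as.integer(min_group)
  loop_min <- as.integer(loop_min); loop_max <- as.integer(loop_max)
  if (min_group < 2 || max_length < 4L * min_group || loop_min < 0 ||
      loop_max < loop_min)
    stop("invalid QGRS parameters")
  if (nchar(s) > 10000L && !isTRUE(force))
    stop("exhaustive QGRS enumeration is restricted to sequences <= 10 kb; ",
         "set force = TRUE to override")

  empty <- data.frame(s1 = integer(), s2 = integer(), s3 = integer(),
                      s4 = integer(), g = integer(), l1 = integer(),
                      l2 = integer(), l3 = integer(), start = integer(),
                      end = integer(), length = integer())
  runs <- find_g_runs(s, min_group)
  if (!nrow(runs)) return(empty)

  g_top <- min(max(runs$length), max_length %/% 4L)
  acc <- list()
  for (g in seq.int(min_group, g_top)) {
    # all 0-based start offsets where a group of size g fits inside a run
    starts <- unlist(lapply(seq_len(nrow(runs)), function(i) {
      if (runs$length[i] < g) return(integer())
      seq.int(runs$offset[i], runs$offset[i] + runs$length[i] - g)
    }))
    if (length(starts) < 1L) next
    starts <- sort(starts)
    for (s1 in starts) {
      # a later group must start within the loop bounds of the previous
      # group's end and still leave its g bases inside the length budget
      nxt <- function(end0) {
        hi <- min(end0 + loop_max, s1 + max_length - g)
        starts[starts >= end0 + loop_min & starts <= hi]
      }
      for (s2 in nxt(s1 + g)) {
        for (s3 in nxt(s2 + g)) {
          for (s4 in nxt(s3 + g)) {
            tot <- s4 + g - s1
            if (tot > max_length) next
            acc[[length(acc) + 1L]] <-
              c(s1, s2, s3, s4, g,
                s2 - (s1 + g), s3 - (s2 + g), s4 - (s3 + g), s1, s4 + g, tot)
          }
        }
      }
    }
  }
  if (!length(acc)) return(empty)
  m <- do.call(rbind, acc)
  out <- data.frame(s1 = m[, 1], s2 = m[, 2], s3 = m[, 3], s4 = m[, 4],
                    g = m[, 5], l1 = m[, 6], l2 = m[, 7], l3 = m[, 8],
                    start = m[, 9], end = m[, 10], length = m[, 11])
  out <- unique(out)
  out <- out[order(out$start, out$end, out$g), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integer G-score of a QGRS candidate
#'
#' Scores a four-group candidate by the QGRS principles: more stacked tetrads
#' score higher, shorter loops score higher than longer ones, and even loop
#' lengths score higher than uneven ones at the same total. The score is a
#' pure function of \code{(g, l1, l2, l3, max_length)}:
#' \deqn{score = 2 g_{max} (g - 1) - \lfloor (2(l_1+l_2+l_3) +
#'   |l_1-l_2| + |l_1-l_3| + |l_2-l_3|)/3 \rfloor}
#' with \eqn{g_{max} = \lfloor max\_length/2 \rfloor - 1}. The tetrad term
#' counts tetrad-tetrad stacking interfaces (g - 1); the loop penalty weights
#' mean loop length twice as much as mean pairwise loop asymmetry, which keeps
#' the score monotone non-increasing in every loop length. The scale constant
#' is calibrated on the published switch-region oligo worked example (G-score
#' 70 at max length 44).
#'
#' @param g guanine-group size (tetrads), >= 2.
#' @param l1,l2,l3 loop lengths in nt, >= 0. All arguments are vectorized.
#' @param max_length maximum candidate span; candidates must satisfy
#'   \code{4*g + l1 + l2 + l3 <= max_length}.
#' @return integer vector of G-scores.
#' @examples
#' qgrs_score(3, 3, 3, 3) > qgrs_score(3, 1, 3, 5)  # evenness reward
#' @export
qgrs_score <- function(g, l1, l2, l3, max_length = 44L) {
  n <- max(length(g), length(l1), length(l2), length(l3))
  g <- rep_len(as.integer(g), n); l1 <- rep_len(as.integer(l1), n)
  l2 <- rep_len(as.integer(l2), n); l3 <- rep_len(as.integer(l3), n)
  if (any(g < 2) || any(c(l1, l2, l3) < 0))
    stop("candidate violates parameter bounds: need g >= 2 and loops >= 0")
  if (any(4L * g + l1 + l2 + l3 > max_length))
    stop("candidate violates parameter bounds: total length exceeds max_length")
  gmax <- as.integer(max_length) %/% 2L - 1L
  penalty <- (2L * (l1 + l2 + l3) +
                abs(l1 - l2) + abs(l1 - l3) + abs(l2 - l3)) %/% 3L
  as.integer(2L * gmax * (g - 1L) - penalty)
}

#' Select the best non-overlapping QGRS motifs
#'
#' Greedy selection by descending G-score (ties broken by leftmost start, then
#' smallest total length) of mutually non-overlapping candidates, mirroring
#' QGRS-style reporting of one best motif per overlapping family.
#'
#' @param candidates data.frame from [enumerate_qgrs()] (one sequence/strand).
#' @param seq the sequence the candidates came from (for the motif string);
#'   optional.
#' @param max_length scoring parameter passed to [qgrs_score()].
#' @param seqname,strand annotations for the output motifs.
#' @return data.frame of motifs as in [scan_canonical()], with
#'   \code{source = "qgrs"} and integer \code{g_score}, sorted by start.
#' @export
select_best_qgrs <- function(candidates, seq = NULL, max_length = 44L,
                             seqname = "seq", strand = "+") {
  if (is.null(candidates) || !nrow(candidates)) return(empty_motifs())
  sc <- qgrs_score(candidates$g, candidates$l1, candidates$l2, candidates$l3,
                   max_length)
  ord <- order(-sc, candidates$start, candidates$length)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (candidates$start[i] < candidates$end[k] &&
          candidates$end[i] > candidates$start[k]) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept <- kept[order(candidates$start[kept])]
  sq <- if (!is.null(seq)) {
    s <- check_dna(seq)
    substring(s, candidates$start[kept] + 1L, candidates$end[kept])
  } else NA_character_
  data.frame(chrom = seqname, start = candidates$start[kept],
             end = candidates$end[kept], strand = strand, seq = sq,
             g_score = sc[kept], source = "qgrs", stringsAsFactors = FALSE,
             row.names = NULL)
}
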