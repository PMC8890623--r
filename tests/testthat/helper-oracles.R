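# Independent oracles and fixture builders used across the test files.
# Every oracle here deliberately takes a different route than the package
# implementation it checks.

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# G-rich alphabet so random sequences actually contain motifs.
random_g_rich <- function(n) {
  random_dna(n, prob = c(0.15, 0.15, 0.55, 0.15))
}

# Character-walk oracle for maximal guanine runs.
naive_g_runs <- function(seq, min_len) {
  ch <- strsplit(toupper(seq), "")[[1]]
  runs <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "G") {
      j <- i
      while (j < length(ch) && ch[j + 1L] == "G") j <- j + 1L
      if (j - i + 1L >= min_len)
        runs[[length(runs) + 1L]] <- c(i - 1L, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(offset = integer(), length = integer()))
  m <- do.call(rbind, runs)
  data.frame(offset = m[, 1], length = m[, 2])
}

# Regular-expression oracle for the canonical motif on one strand, using R's
# TRE engine (the package uses PCRE): same greedy leftmost semantics,
# independent implementation.
tre_scan_oracle <- function(seq, min_run = 3, loop_min = 1, loop_max = 7) {
  s <- toupper(seq)
  pat <- sprintf("G{%d,}([ACGTN]{%d,%d}G{%d,}){3}",
                 min_run, loop_min, loop_max, min_run)
  m <- gregexpr(pat, s, perl = FALSE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  st <- as.integer(m) - 1L
  data.frame(start = st, end = st + as.integer(attr(m, "match.length")))
}

# Full-enumeration oracle for the exact two-sided rank-sum p-value
# (tie-free inputs only).
wilcox_exact_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- rank(c(a, b))
  w_obs <- sum(pooled[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) sum(rank(seq_len(n + m))[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Brute-force overlap oracle: does interval [s, e) (0-based half-open) hit
# any row of the interval table on the same chromosome?
linear_overlap_oracle <- function(chrom, s, e, bed) {
  any(bed$chrom == chrom & bed$start < e & bed$end > s)
}

# Independent reimplementation of the greedy best-QGRS selection rule.
greedy_select_oracle <- function(cands, max_length = 44) {
  sc <- g4burden::qgrs_score(cands$g, cands$l1, cands$l2, cands$l3, max_length)
  df <- cands
  df$score <- sc
  df <- df[order(-df$score, df$start, df$length), , drop = FALSE]
  taken <- df[0, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    if (!nrow(taken) ||
        all(df$start[i] >= taken$end | df$end[i] <= taken$start))
      taken <- rbind(taken, df[i, ])
  }
  taken[order(taken$start), , drop = FALSE]
}

# Write a small mutation table in the default COSMIC-style dialect.
write_fixture_tsv <- function(rows, path) {
  header <- c("ID_sample", "Sample name", "Primary site", "Gene name",
              "Mutation AA", "Mutation genome position",
              "Mutation Description", "Genome-wide screen")
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

smug_oligo <- "GAGCTGGGGTGAGCTGGGCTGAGCTGGGGTGAGCTGGGCTGAGCT"
m1_oligo <- "GAGCTGaGGTGAGCTGGGCTGAGCTGaGGTGAGCTGGGCTGAGCT"
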