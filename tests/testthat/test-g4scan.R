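# Guanine-run detection, canonical motif scanning and QGRS enumeration.

test_that("find_g_runs reports maximal runs and rejects bad input", {
  expect_equal(find_g_runs("GAGGGT", 3),
               data.frame(offset = 2L, length = 3L))
  expect_equal(nrow(find_g_runs("AAAA", 3)), 0L)
  expect_equal(nrow(find_g_runs("GGNGG", 3)), 0L)  # N never counts as G
  expect_equal(find_g_runs("ggggg", 3),
               data.frame(offset = 0L, length = 5L))
  expect_error(find_g_runs("ACGU", 3), "outside")
  expect_error(find_g_runs("ACGT", 0))
})

test_that("find_g_runs matches a character-walk oracle on random sequences", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_g_rich(500)
    expect_equal(find_g_runs(s, 3), naive_g_runs(s, 3))
    expect_equal(find_g_runs(s, 2), naive_g_runs(s, 2))
  }
})

test_that("canonical scan classifies the switch-region oligos", {
  hits <- scan_canonical(smug_oligo, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 5L)
  expect_equal(hits$end, 38L)
  expect_equal(hits$strand, "+")
  # loop lengths of the match, recovered from its own guanine runs
  runs <- find_g_runs(hits$seq, 3)
  loops <- runs$offset[-1] - (runs$offset[-4] + runs$length[-4])
  expect_equal(loops, c(6L, 7L, 6L))
  # two G-to-A interruptions abolish the quadruplex capability
  expect_equal(nrow(scan_canonical(m1_oligo)), 0L)
})

test_that("canonical scan handles degenerate inputs", {
  expect_equal(nrow(scan_canonical("")), 0L)
  expect_equal(nrow(scan_canonical(strrep("A", 200))), 0L)
  expect_error(scan_canonical("ACGT", min_run = 1))
  expect_error(scan_canonical("ACGT", loop_min = 5, loop_max = 2))
})

test_that("canonical scan equals an independent regex engine on random input", {
  set.seed(23)
  for (i in 1:200) {
    s <- random_g_rich(200)
    got <- scan_canonical(s, both_strands = FALSE)
    want <- tre_scan_oracle(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_g_rich(300)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- scan_canonical(s)
    b <- scan_canonical(rc)
    L <- nchar(s)
    mirrored <- data.frame(start = L - b$end, end = L - b$start,
                           strand = ifelse(b$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(a$start, mirrored$start)
    expect_equal(a$end, mirrored$end)
    expect_equal(a$strand, mirrored$strand)
  }
})

test_that("QGRS enumeration finds the expected candidate families", {
  cand <- enumerate_qgrs(smug_oligo)
  expect_gt(nrow(cand), 0)
  loops <- unique(cand[cand$g == 3, c("l1", "l2", "l3")])
  expect_true(any(loops$l1 == 6 & loops$l2 == 7 & loops$l3 == 7))
  expect_true(any(loops$l1 == 7 & loops$l2 == 7 & loops$l3 == 7))
  # all four equal-size groups must sit on guanines
  ch <- strsplit(toupper(smug_oligo), "")[[1]]
  for (r in seq_len(nrow(cand))) {
    offs <- unlist(cand[r, c("s1", "s2", "s3", "s4")])
    g <- cand$g[r]
    expect_true(all(ch[unlist(lapply(offs, function(o) (o + 1):(o + g)))] == "G"))
  }
  # a single contiguous run can host all four groups at loop zero
  polyg <- enumerate_qgrs(strrep("G", 12), loop_min = 0)
  expect_true(any(polyg$g == 3 & polyg$l1 == 0 & polyg$l2 == 0 & polyg$l3 == 0))
  expect_equal(nrow(enumerate_qgrs(strrep("A", 50))), 0L)
})

test_that("QGRS enumeration respects its parameter contract", {
  expect_error(enumerate_qgrs("GGG", max_length = 10, min_group = 3))
  expect_error(enumerate_qgrs(strrep("A", 10001)), "10 kb")
  cand <- enumerate_qgrs(smug_oligo, max_length = 32)
  expect_true(all(cand$length <= 32))
})

test_that("G-score rewards tetrads, short loops and even loops", {
  # evenness at equal total loop length
  expect_gt(qgrs_score(3, 3, 3, 3), qgrs_score(3, 1, 3, 5))
  # monotone non-increasing in each loop length, all else fixed
  for (l in 0:9) {
    expect_gte(qgrs_score(3, l, 4, 4), qgrs_score(3, l + 1, 4, 4))
    expect_gte(qgrs_score(3, 4, l, 4), qgrs_score(3, 4, l + 1, 4))
    expect_gte(qgrs_score(3, 4, 4, l), qgrs_score(3, 4, 4, l + 1))
  }
  # more tetrads score higher
  expect_gt(qgrs_score(4, 2, 2, 2), qgrs_score(3, 2, 2, 2))
  # pure function, vectorized
  expect_equal(qgrs_score(c(3, 4), 1, 1, 1),
               c(qgrs_score(3, 1, 1, 1), qgrs_score(4, 1, 1, 1)))
  expect_error(qgrs_score(3, 20, 20, 20, max_length = 44), "bounds")
  expect_error(qgrs_score(1, 0, 0, 0), "bounds")
})

test_that("best-QGRS selection is greedy, non-overlapping and oracle-equal", {
  best <- select_best_qgrs(enumerate_qgrs(smug_oligo), smug_oligo)
  expect_equal(nrow(best), 1L)
  expect_equal(best$g_score, 70L)
  expect_equal(nrow(select_best_qgrs(NULL)), 0L)

  set.seed(7)
  for (i in 1:30) {
    s <- random_g_rich(120)
    cand <- enumerate_qgrs(s)
    if (!nrow(cand)) next
    got <- select_best_qgrs(cand, s)
    want <- greedy_select_oracle(cand)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$g_score, want$score)
    # selected motifs never overlap
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
  }
})
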