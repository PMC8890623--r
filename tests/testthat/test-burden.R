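# Protein-change parsing, TOP1 domain classification, group assignment and
# control-set selection.

test_that("protein-change strings parse into the full grammar", {
  p <- parse_aa_change(c("p.Y723F", "p.W736*", "p.T729T", "p.G12fs",
                         "p.G12fs*5", "", "c.100A>T", "p.?"))
  expect_equal(p$kind, c("missense", "nonsense", "synonymous", "frameshift",
                         "frameshift", "other", "other", "other"))
  expect_equal(p$pos, c(723L, 736L, 729L, 12L, 12L, NA, NA, NA))
  expect_equal(p$ref[1:2], c("Y", "W"))
  expect_equal(p$alt[1:2], c("F", "*"))
  expect_equal(nrow(parse_aa_change(character())), 0L)
})

test_that("domain classification is total and respects printed boundaries", {
  cases <- data.frame(kind = c("missense", "missense", "missense", "missense",
                               "missense", "missense", "nonsense",
                               "frameshift", "synonymous", "other"),
                      pos = c(723L, 1L, 214L, 215L, 634L, 635L, 10L, 765L,
                              729L, NA))
  got <- classify_domain(cases)
  expect_equal(got, c("C-Ter", "N-Ter", "N-Ter", "Core", "Core", "Linker",
                      "Stop", "Stop", "none", "none"))
  # out-of-range missense maps to none
  expect_equal(classify_domain(data.frame(kind = "missense", pos = 800L)),
               "none")
  expect_true(all(got %in% c("N-Ter", "Core", "Linker", "C-Ter", "Stop",
                             "none")))
  expect_error(check_domain_map(data.frame(domain = "A", aa_lo = 5L,
                                           aa_hi = 1L)))
})

make_top1_records <- function(sample_id, aa) {
  data.frame(sample_id = sample_id, sample_code = sample_id,
             tumor_type = "lung", gene = "TOP1", aa_change = aa,
             chrom = "20", start = seq_along(aa), end = seq_along(aa),
             mutation_class = "substitution", genome_screen = "y",
             stringsAsFactors = FALSE)
}

test_that("sample group assignment follows the precedence rule", {
  rec <- rbind(make_top1_records(c("s1"), "p.Y723F"),
               make_top1_records(c("s2", "s2"), c("p.A100V", "p.Q500*")),
               make_top1_records("s3", "p.T729T"))
  prof <- per_sample_totals(rec)
  prof <- suppressMessages(assign_top1_groups(prof, rec))
  expect_equal(prof$top1_group[prof$sample_id == "s1"], "C-Ter")
  expect_equal(prof$top1_group[prof$sample_id == "s2"], "Stop")
  expect_equal(prof$top1_group[prof$sample_id == "s3"], "none")
})

test_that("planted groups are recovered for single-change samples", {
  gen <- make_genome(chrom_length = 30000, n_motifs = 10, seed = 8)
  co <- make_cohort(cohort_spec(n_background = 30,
                                group_counts = c("N-Ter" = 4, "Linker" = 4,
                                                 "Core" = 4, "C-Ter" = 4,
                                                 "Stop" = 4)),
                    gen, seed = 21)
  rec <- dedupe_samples(co$records)
  prof <- assign_top1_groups(per_sample_totals(rec), rec)
  m <- match(prof$sample_id, co$truth$sample_id)
  expect_equal(prof$top1_group, co$truth$group[m])
  # the five groups partition the TOP1-mutant samples
  sizes <- table(prof$top1_group)
  expect_equal(sum(sizes[c("N-Ter", "Linker", "Core", "C-Ter", "Stop")]),
               sum(co$truth$group != "none"))
})

test_that("group pooling concatenates disjoint memberships", {
  prof <- data.frame(sample_id = sprintf("s%02d", 1:10),
                     top1_group = c(rep("N-Ter", 2), rep("Linker", 3),
                                    rep("C-Ter", 2), rep("Stop", 1),
                                    rep("none", 2)),
                     stringsAsFactors = FALSE)
  pools <- combine_groups(prof)
  expect_equal(length(pools$NLC), 5L)
  expect_equal(length(pools$CS), 3L)
  expect_length(intersect(pools$NLC, pools$CS), 0L)
  expect_equal(combine_groups(prof, list()), list())
  expect_error(combine_groups(prof, list(A = "Stop", B = c("Stop", "C-Ter"))),
               "overlapping")
})

test_that("Ran selection is seeded, uniform and order-invariant", {
  prof <- data.frame(sample_id = sprintf("s%02d", 1:10),
                     sample_code = sprintf("s%02d", 1:10),
                     tumor_type = "lung", total_mutations = 1:10,
                     stringsAsFactors = FALSE)
  expect_equal(select_ran(prof, 3, seed = 42), select_ran(prof, 3, seed = 42))
  expect_equal(select_ran(prof, 10, seed = 1), sort(prof$sample_id))
  expect_error(select_ran(prof, 11, seed = 1), "exceeds")
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(select_ran(shuffled, 4, seed = 7), select_ran(prof, 4, seed = 7))

  # empirical inclusion probability n/N across many seeds
  counts <- integer(10)
  for (s in 1:10000) {
    picked <- select_ran(prof, 3, seed = s)
    counts[match(picked, prof$sample_id)] <-
      counts[match(picked, prof$sample_id)] + 1L
  }
  expect_true(all(abs(counts / 10000 - 0.3) < 0.02))
})

test_that("Ran_H selection honors the two-stage contract", {
  set.seed(99)
  n <- 2000
  prof <- data.frame(sample_id = sprintf("h%04d", 1:n),
                     sample_code = sprintf("h%04d", 1:n),
                     tumor_type = "lung",
                     total_mutations = c(rep(50L, 300),
                                         rep(700L, n - 300)),
                     stringsAsFactors = FALSE)
  got <- select_ran_high(prof, min_mut = 400, pool_size = 1500, n = 300,
                         seed = 3)
  expect_length(got, 300L)
  expect_true(all(prof$total_mutations[match(got, prof$sample_id)] >= 400))
  expect_equal(got, select_ran_high(prof, seed = 3))
  expect_error(select_ran_high(prof, min_mut = 1e6, seed = 1), "cannot select")
  # small qualifying set: pool collapses to all qualifying samples
  small <- prof[1:750, ]
  expect_message(got2 <- select_ran_high(small, seed = 5), "pool is all")
  expect_true(all(small$total_mutations[match(got2, small$sample_id)] >= 400))
})
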