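# Mutation-table parsing, sample filters and per-sample totals.

fixture_rows <- function() {
  list(
    c("S1", "S1", "lung", "TP53", "p.R175H", "17:7675088-7675088",
      "Substitution - Missense", "y"),
    c("S1", "S1", "lung", "KRAS", "p.G12D", "12:25245350-25245350",
      "Substitution - Missense", "y"),
    c("S2", "S2", "skin", "BRAF", "p.V600E", "7:140753336-140753336",
      "Substitution - Missense", "n"),
    c("S3", "S3", "lung", "TOP1", "p.Y723F", "20:41095280-41095280",
      "Substitution - Missense", "y"),
    c("S4", "S4", "skin", "NRAS", "p.Q61K", "1:114713909-114713909",
      "Substitution - Missense", "n"))
}

test_that("reader keeps only genome-wide screens and drops bad coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_tsv(do.call(rbind, fixture_rows()), path)
  rec <- read_mutation_export(path)
  expect_equal(nrow(rec), 3L)
  expect_true(all(rec$genome_screen == "y"))
  expect_equal(rec$sample_id, c("S1", "S1", "S3"))
  expect_equal(rec$start[1], 7675088L)
  expect_equal(rec$mutation_class[1], "substitution")

  rows <- fixture_rows()
  rows[[2]][6] <- "12:oops"
  write_fixture_tsv(do.call(rbind, rows), path)
  expect_message(rec2 <- read_mutation_export(path), "dropped 1")
  expect_equal(nrow(rec2), 2L)
})

test_that("reader validates configuration and empty input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("ID_sample\tGene name", path)
  expect_error(suppressWarnings(read_mutation_export(path)), "empty|missing")
  write_fixture_tsv(do.call(rbind, fixture_rows()), path)
  expect_error(read_mutation_export(path,
               columns = cosmic_columns(sample_id = "No Such Column")),
               "missing")
  expect_error(cosmic_columns(bogus_field = "x"), "unknown")
})

test_that("duplicate identical rows collapse unless disabled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- fixture_rows()[c(1, 1, 2)]
  write_fixture_tsv(do.call(rbind, rows), path)
  expect_message(rec <- read_mutation_export(path), "collapsed 1")
  expect_equal(nrow(rec), 2L)
  rec2 <- read_mutation_export(path, dedup_rows = FALSE)
  expect_equal(nrow(rec2), 3L)
})

test_that("samples with one code but several tumor types are removed", {
  rec <- data.frame(
    sample_id = c("a", "b", "b", "c"), sample_code = c("S7", "S7", "S7", "S9"),
    tumor_type = c("lung", "skin", "skin", "lung"),
    gene = "X", aa_change = "", chrom = "1", start = 1:4, end = 1:4,
    mutation_class = "substitution", genome_screen = "y",
    stringsAsFactors = FALSE)
  expect_message(out <- dedupe_samples(rec), "removed 1")
  expect_equal(out$sample_code, "S9")

  uniq <- rec[rec$sample_code == "S9", ]
  rownames(uniq) <- NULL
  expect_equal(dedupe_samples(uniq), uniq)
})

test_that("dedupe matches a group-by-then-filter oracle on random tables", {
  set.seed(4)
  for (i in 1:20) {
    n <- 60
    rec <- data.frame(
      sample_id = sample(sprintf("id%02d", 1:12), n, replace = TRUE),
      sample_code = sample(sprintf("code%d", 1:8), n, replace = TRUE),
      tumor_type = sample(c("lung", "skin", "colon"), n, replace = TRUE),
      gene = "X", aa_change = "", chrom = "1",
      start = seq_len(n), end = seq_len(n),
      mutation_class = "substitution", genome_screen = "y",
      stringsAsFactors = FALSE)
    got <- suppressMessages(dedupe_samples(rec))
    keep <- vapply(split(rec$tumor_type, rec$sample_code),
                   function(x) length(unique(x)) == 1L, TRUE)
    want <- rec[rec$sample_code %in% names(keep)[keep], ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("per-sample totals aggregate records and conserve counts", {
  rec <- data.frame(
    sample_id = rep(c("A", "B", "C"), c(2, 5, 1)),
    sample_code = rep(c("A", "B", "C"), c(2, 5, 1)),
    tumor_type = "lung", gene = "X", aa_change = "", chrom = "1",
    start = 1:8, end = 1:8, mutation_class = "substitution",
    genome_screen = "y", stringsAsFactors = FALSE)
  prof <- per_sample_totals(rec)
  expect_equal(prof$total_mutations, c(2L, 5L, 1L))
  expect_equal(prof$top1_group, rep("none", 3))
  expect_equal(sum(prof$total_mutations), nrow(rec))
  expect_equal(nrow(per_sample_totals(rec[0, ])), 0L)
})

test_that("read -> dedupe -> totals is idempotent on its own output", {
  gen <- make_genome(chrom_length = 20000, n_motifs = 5, seed = 2)
  co <- make_cohort(cohort_spec(n_background = 20,
                                group_counts = c("N-Ter" = 1, "Linker" = 1,
                                                 "Core" = 1, "C-Ter" = 2,
                                                 "Stop" = 2)),
                    gen, seed = 3)
  once <- per_sample_totals(dedupe_samples(co$records))
  rec2 <- dedupe_samples(dedupe_samples(co$records))
  expect_equal(per_sample_totals(rec2), once)
  expect_equal(once$total_mutations,
               co$truth$total[match(once$sample_id, co$truth$sample_id)])
})
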