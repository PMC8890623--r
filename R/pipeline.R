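# End-to-end orchestration: scan -> load -> assign -> intersect -> compare,
# with an output manifest capturing parameters, seeds and input checksums.

#' Run the full mutation-burden-at-G4 analysis
#'
#' Stages: (1) PONDS scan of the reference FASTA; (2) mutation-table load
#' with screen filtering and sample deduplication; (3) TOP1 domain-group
#' assignment; (4) mutation/PONDS intersection and per-sample percent-at-G4;
#' (5) group pooling, control-set selection and rank-sum comparisons. Outputs
#' (PONDS BED, profiles TSV, percent TSV, summary TSV and a JSON manifest)
#' are written to \code{config$out_dir}; reruns with the same config are
#' byte-identical. Any stage failure errors with the failing stage named.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \code{fasta} (reference FASTA path), \code{mutations} (mutation TSV
#'   path), \code{out_dir}; optional \code{mode} ("canonical"/"qgrs"),
#'   \code{scan} (list of extra [ponds_scan()] arguments), \code{gene},
#'   \code{domains} (path to a TSV domain map: columns gene, domain, aa_lo,
#'   aa_hi), \code{ran_n}, \code{ran_seed}, \code{ran_high} (logical),
#'   \code{ran_high_seed}, \code{min_mut}, \code{pool_size},
#'   \code{pools} (named list of group vectors).
#' @return invisibly, a list with \code{summary}, \code{profiles},
#'   \code{ponds}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  for (key in c("fasta", "mutations", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- if (is.null(config$mode)) "canonical" else config$mode
  gene <- if (is.null(config$gene)) "TOP1" else config$gene
  ran_n <- if (is.null(config$ran_n)) 300L else as.integer(config$ran_n)
  ran_seed <- if (is.null(config$ran_seed)) stop("config is missing 'ran_seed'")
              else as.integer(config$ran_seed)

  ponds <- stage("g4scan", do.call(ponds_scan, c(
    list(fasta = config$fasta, mode = mode,
         out = file.path(config$out_dir, "ponds.bed")),
    config$scan)))

  records <- stage("cohort", {
    r <- read_mutation_export(config$mutations)
    dedupe_samples(r)
  })
  profiles <- stage("cohort", per_sample_totals(records))

  profiles <- stage("burden", {
    map <- if (!is.null(config$domains)) {
      if (!file.exists(config$domains))
        stop("domain map file not found: ", config$domains)
      check_domain_map(utils::read.delim(config$domains))
    } else top1_domain_map(gene)
    assign_top1_groups(profiles, records, gene = gene, map = map)
  })

  profiles <- stage("overlap", {
    idx <- build_ponds_index(ponds)
    add_pct_at_g4(profiles, records, idx)
  })

  summary <- stage("stats", {
    pools <- if (is.null(config$pools))
      list(NLC = c("N-Ter", "Linker", "Core"), CS = c("C-Ter", "Stop"))
      else config$pools
    groups <- c(
      lapply(stats::setNames(nm = unique(profiles$top1_group[
        profiles$top1_group != "none"])), function(g)
          sort(profiles$sample_id[profiles$top1_group == g])),
      combine_groups(profiles, pools))
    controls <- list(Ran = select_ran(profiles, n = ran_n, seed = ran_seed))
    if (isTRUE(config$ran_high)) {
      controls$Ran_H <- select_ran_high(
        profiles,
        min_mut = if (is.null(config$min_mut)) 400L else config$min_mut,
        pool_size = if (is.null(config$pool_size)) 1500L else config$pool_size,
        n = ran_n,
        seed = if (is.null(config$ran_high_seed)) ran_seed + 1L
               else as.integer(config$ran_high_seed))
    }
    summarize_fig5(profiles, groups, controls)
  })

  prof_path <- file.path(config$out_dir, "profiles.tsv")
  utils::write.table(profiles, prof_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pct_path <- file.path(config$out_dir, "pct.tsv")
  utils::write.table(
    profiles[c("sample_id", "total_mutations", "pct_at_g4")],
    pct_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sum_path <- file.path(config$out_dir, "summary.tsv")
  utils::write.table(summary$comparisons, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grp_path <- file.path(config$out_dir, "groups.tsv")
  utils::write.table(summary$groups, grp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    package = "g4burden",
    version = as.character(utils::packageVersion("g4burden")),
    mode = mode, gene = gene,
    seeds = list(ran = ran_seed,
                 ran_high = if (isTRUE(config$ran_high))
                   (if (is.null(config$ran_high_seed)) ran_seed + 1L
                    else as.integer(config$ran_high_seed)) else NULL),
    parameters = config$scan,
    inputs = list(fasta = unname(tools::md5sum(config$fasta)),
                  mutations = unname(tools::md5sum(config$mutations))),
    outputs = basename(c("ponds.bed", prof_path, pct_path, sum_path,
                         grp_path)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(summary = summary, profiles = profiles, ponds = ponds,
                 manifest = manifest))
}
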