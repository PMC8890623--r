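# Ground-truthed synthetic inputs: genomes with implanted G4 motifs, tumor
# cohorts with planted TOP1-group structure and G4-mutation enrichment, and
# simulated Luria-Delbruck fluctuation experiments. Every generator is a pure
# function of (spec, seed).

# Break every guanine run (and, via C runs, every reverse-strand guanine run)
# of min_run or more in a character vector of bases, so the background can
# never form a canonical motif on either strand.
break_g_runs <- function(bases, min_run = 3L) {
  s <- paste(bases, collapse = "")
  for (ch in c("G", "C")) {
    m <- gregexpr(sprintf("%s{%d,}", ch, min_run), s)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      off <- as.integer(m[i]); len <- attr(m, "match.length")[i]
      kill <- seq.int(off + min_run - 1L, off + len - 1L, by = min_run)
      bases[kill] <- if (ch == "G") "T" else "A"
    }
  }
  bases
}

#' Generate a genome with implanted G4 motifs at known coordinates
#'
#' The background is random sequence post-processed so that no guanine run of
#' \code{min_run} or more survives, hence it contains no spurious canonical
#' motif; \code{n_motifs} copies of the template are then implanted at
#' recorded, well-separated coordinates (a fraction on the reverse strand,
#' i.e. implanted as the reverse complement) with a one-base T buffer on each
#' side so implant coordinates are exactly recoverable. The generated genome
#' is verified against [scan_canonical()]: scanning must reproduce the truth
#' intervals exactly, else generation errors.
#'
#' @param n_chrom number of chromosomes (default 1).
#' @param chrom_length length of each chromosome in nt.
#' @param n_motifs motifs implanted per chromosome.
#' @param motif canonical-motif template (default a 24-nt four-run motif with
#'   4-nt loops).
#' @param revcomp_fraction fraction of implants on the reverse strand
#'   (default 0.5).
#' @param min_run guanine-run length that must not occur in the background.
#' @param seed integer seed.
#' @param out_fasta,out_bed optional output paths (FASTA genome, truth BED).
#' @return list with \code{genome} (\link[Biostrings]{DNAStringSet}) and
#'   \code{truth} (BED-like data.frame of implants with strand).
#' @export
make_genome <- function(n_chrom = 1L, chrom_length = 100000L, n_motifs = 25L,
                        motif = "GGGTCTAGGGTCTAGGGTCTAGGG",
                        revcomp_fraction = 0.5, min_run = 3L, seed = 1L,
                        out_fasta = NULL, out_bed = NULL) {
  motif <- check_dna(motif)
  mlen <- nchar(motif)
  gap <- mlen + 20L  # implants separated by more than any loop span
  if (n_motifs > 0 && (n_motifs * (mlen + 2L * gap)) > chrom_length)
    stop("cannot place ", n_motifs, " motifs of length ", mlen,
         " in a chromosome of ", chrom_length, " nt")
  if (nrow(scan_canonical(motif, min_run = min_run)) < 1L)
    stop("motif template is not a canonical G4 motif")

  res <- with_seed(seed, {
    lapply(seq_len(n_chrom), function(ci) {
      bases <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
      bases <- break_g_runs(bases, min_run)
      truth <- NULL
      if (n_motifs > 0) {
        # rejection-sample well-separated implant start positions (1-based)
        repeat {
          pos <- sort(sample.int(chrom_length - mlen - 1L, n_motifs) + 1L)
          if (n_motifs == 1L || min(diff(pos)) >= mlen + gap) break
        }
        minus <- rep(FALSE, n_motifs)
        n_minus <- round(revcomp_fraction * n_motifs)
        if (n_minus > 0) minus[sample.int(n_motifs, n_minus)] <- TRUE
        for (k in seq_len(n_motifs)) {
          ins <- if (minus[k]) revcomp_chr(motif) else motif
          bases[pos[k]:(pos[k] + mlen - 1L)] <- strsplit(ins, "")[[1]]
          if (pos[k] > 1L) bases[pos[k] - 1L] <- "T"
          if (pos[k] + mlen <= chrom_length) bases[pos[k] + mlen] <- "T"
        }
        truth <- data.frame(chrom = paste0("chr", ci),
                            start = pos - 1L, end = pos + mlen - 1L,
                            name = "implant", score = 0L,
                            strand = ifelse(minus, "-", "+"),
                            stringsAsFactors = FALSE)
      }
      list(seq = paste(bases, collapse = ""), truth = truth)
    })
  })
  genome <- Biostrings::DNAStringSet(vapply(res, `[[`, "", "seq"))
  names(genome) <- paste0("chr", seq_len(n_chrom))
  truth <- do.call(rbind, lapply(res, `[[`, "truth"))
  if (is.null(truth))
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(), score = integer(),
                        strand = character(), stringsAsFactors = FALSE)

  found <- do.call(rbind, lapply(seq_len(n_chrom), function(ci)
    scan_canonical(as.character(genome[[ci]]), min_run = min_run,
                   seqname = paste0("chr", ci))))
  same <- if (is.null(found)) !nrow(truth)
          else nrow(found) == nrow(truth) &&
               all(found$start == truth$start & found$end == truth$end &
                   found$chrom == truth$chrom & found$strand == truth$strand)
  if (!same) stop("generation error: scanner output does not match implants")

  if (!is.null(out_fasta)) Biostrings::writeXStringSet(genome, out_fasta)
  if (!is.null(out_bed) && nrow(truth)) write_bed(truth, out_bed)
  list(genome = genome, truth = truth)
}

#' Specification of a synthetic tumor cohort
#'
#' Defaults emulate the study conditions at desk scale: 300 background
#' samples whose per-sample totals follow a negative binomial with median 79
#' (heavy right tail), domain-group samples scaled to roughly a tenth of the
#' published group sizes except the catalytic-defect groups (15 C-Ter + 15
#' Stop), a 12-fold count multiplier for all TOP1-mutant groups, and a 5-fold
#' G4-placement enrichment for the C-Ter and Stop groups only.
#'
#' @param n_background number of background (TOP1-wild-type) samples.
#' @param group_counts named counts for N-Ter, Linker, Core, C-Ter, Stop.
#' @param median_background target median per-sample mutation count.
#' @param dispersion negative-binomial size parameter (smaller = heavier
#'   tail).
#' @param multiplier count multiplier for TOP1-mutant groups (default 12).
#' @param enrichment named per-group G4-placement probability multipliers
#'   (>= 1); background samples always have factor 1.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_background = 300L,
                        group_counts = c("N-Ter" = 6L, "Linker" = 3L,
                                         "Core" = 10L, "C-Ter" = 15L,
                                         "Stop" = 15L),
                        median_background = 79,
                        dispersion = 1.3,
                        multiplier = 12,
                        enrichment = c("N-Ter" = 1, "Linker" = 1, "Core" = 1,
                                       "C-Ter" = 5, "Stop" = 5)) {
  grp <- c("N-Ter", "Linker", "Core", "C-Ter", "Stop")
  stopifnot(all(grp %in% names(group_counts)), all(grp %in% names(enrichment)))
  if (any(group_counts < 0) || any(enrichment < 1) || multiplier <= 0 ||
      n_background < 0 || median_background <= 0 || dispersion <= 0)
    stop("invalid cohort spec")
  structure(list(n_background = as.integer(n_background),
                 group_counts = group_counts[grp],
                 median_background = median_background,
                 dispersion = dispersion, multiplier = multiplier,
                 enrichment = enrichment[grp]),
            class = "cohort_spec")
}

# mu of a negative binomial (size = dispersion) whose median is the target.
nb_mu_for_median <- function(med, size) {
  f <- function(mu) stats::qnbinom(0.5, size = size, mu = mu) - med
  lo <- med; hi <- med * 4
  while (f(hi) < 0) hi <- hi * 2
  while (f(lo) > 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi))$root
}

# Draw 1-based positions uniformly over the bases covered by a set of
# disjoint intervals (given as 0-based half-open data.frame rows).
sample_positions <- function(iv, n) {
  if (!n) return(list(chrom = character(), pos = integer()))
  w <- iv$end - iv$start
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  off <- floor(stats::runif(n) * w[pick])
  list(chrom = iv$chrom[pick], pos = as.integer(iv$start[pick] + off + 1L))
}

# Complement of intervals within chromosomes of the given lengths
# (0-based half-open in and out).
complement_intervals <- function(iv, seqlens) {
  out <- lapply(names(seqlens), function(ch) {
    sub <- iv[iv$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    starts <- c(0L, sub$end)
    ends <- c(sub$start, seqlens[[ch]])
    keep <- ends > starts
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate a synthetic tumor cohort with planted structure
#'
#' For each sample, a total mutation count is drawn from its group's
#' negative-binomial distribution (background median as specified;
#' TOP1-mutant groups with the spec multiplier applied to the mean).
#' Each mutation lands inside a PONDS interval with probability
#' \eqn{f p / (f p + (1 - p))}, where p is the genome's PONDS base fraction
#' and f the group's enrichment factor, and is otherwise placed uniformly
#' outside; within the chosen stratum, positions are uniform over bases.
#' TOP1-mutant samples carry one TOP1 record whose protein-change string is
#' synthesized to match the planted group (random missense in the domain's
#' residue range; Stop samples alternate nonsense and frameshift spellings).
#' All records are flagged \code{genome_screen = "y"}.
#'
#' @param spec a [cohort_spec()].
#' @param genome result of [make_genome()] (its \code{truth} intervals are
#'   the PONDS track).
#' @param seed integer seed.
#' @param out_tsv optional path for the mutation table (COSMIC-style columns).
#' @return list with \code{records} (mutation-record data.frame as returned
#'   by [read_mutation_export()]), \code{truth} (per-sample data.frame:
#'   \code{sample_id}, \code{group}, \code{total}, \code{n_in_ponds}), and
#'   \code{ponds_fraction}.
#' @export
make_cohort <- function(spec, genome, seed = 1L, out_tsv = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  ponds <- genome$truth
  seqlens <- stats::setNames(Biostrings::width(genome$genome),
                             names(genome$genome))
  p <- sum(ponds$end - ponds$start) / sum(seqlens)
  if (p <= 0 || p >= 1) stop("PONDS fraction must be in (0,1)")
  nonponds <- complement_intervals(ponds, as.list(seqlens))

  groups <- rep(names(spec$group_counts), spec$group_counts)
  n_mut <- length(groups)
  n <- spec$n_background + n_mut
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- c(rep("none", spec$n_background), groups)

  mu_bg <- nb_mu_for_median(spec$median_background, spec$dispersion)
  res <- with_seed(seed, {
    mu <- ifelse(group == "none", mu_bg, mu_bg * spec$multiplier)
    totals <- stats::rnbinom(n, size = spec$dispersion, mu = mu) + 1L
    f <- ifelse(group == "none", 1, spec$enrichment[group])
    prob_in <- f * p / (f * p + (1 - p))
    n_in <- stats::rbinom(n, totals, prob_in)

    sid <- rep(sample_id, totals)
    in_ponds <- unlist(lapply(seq_len(n), function(i)
      c(rep(TRUE, n_in[i]), rep(FALSE, totals[i] - n_in[i]))))
    pin <- sample_positions(ponds, sum(n_in))
    pout <- sample_positions(nonponds, sum(totals) - sum(n_in))
    chrom <- character(length(sid)); pos <- integer(length(sid))
    chrom[in_ponds] <- pin$chrom; pos[in_ponds] <- pin$pos
    chrom[!in_ponds] <- pout$chrom; pos[!in_ponds] <- pout$pos

    rec <- data.frame(sample_id = sid, sample_code = sid,
                      tumor_type = "synthetic_tumor",
                      gene = sprintf("GENE%03d",
                                     sample.int(500, length(sid),
                                                replace = TRUE)),
                      aa_change = "", chrom = chrom,
                      start = pos, end = pos,
                      mutation_class = "substitution", genome_screen = "y",
                      stringsAsFactors = FALSE)

    # one TOP1 record per mutant sample, consistent with its planted group
    aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V")
    dmap <- top1_domain_map()
    first_row <- match(sample_id, rec$sample_id)
    for (i in which(group != "none")) {
      g <- group[i]
      if (g == "Stop") {
        posn <- sample.int(765L, 1L)
        ch <- if (stats::runif(1) < 0.5)
                sprintf("p.%s%d*", sample(aa, 1), posn)
              else sprintf("p.%s%dfs", sample(aa, 1), posn)
      } else {
        d <- dmap[dmap$domain == g, ]
        posn <- sample(seq.int(d$aa_lo, d$aa_hi), 1L)
        pair <- sample(aa, 2L)
        ch <- sprintf("p.%s%d%s", pair[1], posn, pair[2])
      }
      rec$gene[first_row[i]] <- "TOP1"
      rec$aa_change[first_row[i]] <- ch
    }
    list(records = rec,
         truth = data.frame(sample_id = sample_id, group = group,
                            total = as.integer(totals),
                            n_in_ponds = as.integer(n_in),
                            stringsAsFactors = FALSE))
  })
  res$ponds_fraction <- p
  if (!is.null(out_tsv)) write_cohort_tsv(res$records, out_tsv)
  res
}

#' Write mutation records as a COSMIC-style mutant-export TSV
#'
#' Emits the column names of the default [cosmic_columns()] map, so the file
#' round-trips through [read_mutation_export()].
#'
#' @param records mutation-record data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_cohort_tsv <- function(records, path) {
  out <- data.frame("ID_sample" = records$sample_id,
                    "Sample name" = records$sample_code,
                    "Primary site" = records$tumor_type,
                    "Gene name" = records$gene,
                    "Mutation AA" = records$aa_change,
                    "Mutation genome position" =
                      sprintf("%s:%d-%d", records$chrom, records$start,
                              records$end),
                    "Mutation Description" = records$mutation_class,
                    "Genome-wide screen" = records$genome_screen,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate Luria-Delbruck fluctuation experiments
#'
#' Per culture, the number of mutational events is Poisson(m); each event
#' occurs at a uniformly chosen point of the exponential growth (so the
#' probability of striking with d doublings still to go is 2^-(d+1)) and
#' contributes a clone of 2^d mutant cells, truncated at \code{n_total}. The
#' culture's mutant count is the sum of its clone sizes, reproducing the
#' heavy-tailed ("jackpot") Luria-Delbruck distribution with
#' P(count = 0) = exp(-m).
#'
#' @param m expected mutational events per culture (>= 0).
#' @param n_cultures number of parallel cultures.
#' @param n_total viable cells per culture at plating.
#' @param seed integer seed.
#' @return data.frame with one row per culture: \code{strain},
#'   \code{mutant_count}, \code{cells_plated}.
#' @export
simulate_luria_delbruck <- function(m, n_cultures = 24L, n_total = 2e8,
                                    seed = 1L) {
  if (m < 0 || n_total < 1 || n_cultures < 1) stop("invalid parameters")
  counts <- with_seed(seed, {
    vapply(seq_len(n_cultures), function(i) {
      k <- stats::rpois(1L, m)
      if (!k) return(0)
      d <- floor(-log2(stats::runif(k)))          # doublings still to go
      sum(pmin(2^d, n_total))
    }, 0)
  })
  data.frame(strain = "sim", mutant_count = counts, cells_plated = n_total,
             stringsAsFactors = FALSE)
}
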