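# g4burden

Somatic mutations in *TOP1* (DNA topoisomerase 1) are associated with
hypermutated tumors, and in particular with an excess of mutations at
G-quadruplex-capable sequences — guanine-run repeats that can fold into
four-stranded G4 DNA. `g4burden` is an R package for the computational side
of that analysis: it detects G4-capable sequence motifs, turns them into a
genomic annotation track, intersects somatic mutation tables with that
track, and compares per-sample mutation burden between *TOP1* domain-mutant
groups and random control sets. It also implements the fluctuation-assay
statistics (Luria–Delbrück method of the median) used to measure
recombination and mutation rates in the companion yeast experiments.

It is aimed at genome-instability researchers who want a tested, seeded,
fully offline-reproducible version of this pipeline: every stage can be
exercised against a synthetic-data generator with known ground truth.

## What it computes

**G4 motif detection.** Two detectors over FASTA input:

- *canonical*: greedy regular-expression matching of
  `G{3,}(N{1,7}G{3,}){3}` on both strands (the minimal
  `GGGN1-7GGGN1-7GGGN1-7GGG` quadruplex definition);
- *QGRS*: exhaustive enumeration of four equal-size guanine groups
  (`G{g}N{l1}G{g}N{l2}G{g}N{l3}G{g}`, g ≥ 3, loops 0–10, total ≤ 44 nt by
  default) with an integer G-score rewarding more stacked tetrads, shorter
  loops, and even loops:

  ```
  gmax  = floor(max_length / 2) - 1
  score = 2 * gmax * (g - 1)
          - floor((2*(l1+l2+l3) + |l1-l2| + |l1-l3| + |l2-l3|) / 3)
  ```

  calibrated so the published immunoglobulin switch-region oligo (SμG)
  scores 70 under the stated parameters.

Overlapping hits from either strand are merged into disjoint PONDS
("potential non-B DNA-forming sequences") intervals and written as BED.

**Mutation burden at G4.** A COSMIC-mutant-export-style TSV is filtered to
genome-wide screens, ambiguous sample codes are removed, per-sample totals
are counted, *TOP1* protein changes are classified into N-Ter (a.a. 1–214),
Core (215–634), Linker (635–711), C-Ter (712–765) and Stop
(nonsense/frameshift anywhere), and each sample's percent of mutations
overlapping PONDS is computed. Domain groups, pooled groups (N-Ter ∪ Linker
∪ Core vs C-Ter ∪ Stop), and seeded random control sets (Ran; Ran_H drawn
from a pool of high-burden samples) are compared with two-sided Wilcoxon
rank-sum tests.

**Fluctuation assays.** From mutant counts over 12–36 parallel cultures,
the expected number of mutational events per culture m solves the
Lea–Coulson median equation r̃/m − ln m = 1.24; the rate is m divided by
viable cells per culture, with a 95% CI from
σ_ln m = 1.225 m^(−0.315)/√C. Two rates differ significantly when their
95% CIs do not overlap.

## Worked example

```r
library(g4burden)

## the published 45-nt switch-region oligo
smug <- "GAGCTGGGGTGAGCTGGGCTGAGCTGGGGTGAGCTGGGCTGAGCT"
scan_canonical(smug)
#>   chrom start end strand                               seq g_score    source
#> 1   seq     5  38      + GGGGTGAGCTGGGCTGAGCTGGGGTGAGCTGGG      NA canonical
select_best_qgrs(enumerate_qgrs(smug), smug)
#>   chrom start end strand                               seq g_score source
#> 1   seq     5  38      + GGGGTGAGCTGGGCTGAGCTGGGGTGAGCTGGG      70   qgrs
```

The oligo holds one G4 motif (0-based interval [5, 38)); its best QGRS
arrangement scores G-score 70, matching the published value.

```r
## synthetic cohort with planted C-Ter/Stop enrichment at G4
gen  <- make_genome(chrom_length = 50000, n_motifs = 40, seed = 1)
spec <- cohort_spec(n_background = 150,
                    group_counts = c("N-Ter" = 3, "Linker" = 2, "Core" = 5,
                                     "C-Ter" = 8, "Stop" = 8))
co   <- make_cohort(spec, gen, seed = 2)
rec  <- dedupe_samples(co$records)
prof <- assign_top1_groups(per_sample_totals(rec), rec)
prof <- add_pct_at_g4(prof, rec, build_ponds_index(gen$truth))
compare_pooled(prof, combine_groups(prof)$CS, select_ran(prof, 100, seed = 3),
               metric = "pct_at_g4", names = c("CS", "Ran"))
#> Wilcoxon rank-sum: CS (n=16, median=8.90489) vs Ran (n=100, median=1.98777)
#>   U = 1499, two-sided p = 2.002e-08  [normal-approximation-with-tie-correction]
```

The pooled C-Ter/Stop samples carry ~9% of their mutations at G4 versus ~2%
for the random control — the planted 5-fold enrichment, recovered by the
pipeline.

```r
## fluctuation assay: rate recovery from simulated cultures
d <- simulate_luria_delbruck(m = 2, n_cultures = 24, n_total = 2e8, seed = 4)
estimate_rate(d$mutant_count, d$cells_plated)
#> Fluctuation rate estimate (lc-median, 24 cultures):
#>   m = 2.212, rate = 1.106e-08 per cell [95% CI 7.552e-09 - 1.62e-08]
```

The true simulated rate, 2/2e8 = 1e-08 per cell, lies inside the 95% CI.

`run_pipeline(config)` wires the stages end to end (FASTA + mutation TSV in;
PONDS BED, profile/percent/summary TSVs and a JSON manifest with all seeds
and input checksums out). See the methods vignette
(`vignettes/g4-mutation-burden.Rmd`) for the models, parameter choices and
limitations.

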