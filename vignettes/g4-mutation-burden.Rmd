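---
title: "Methods: mutation burden at G-quadruplex motifs and fluctuation-assay rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation burden at G-quadruplex motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4burden)
```

## Scope and model

`g4burden` implements a three-part analysis:

1. **G4 motif detection and PONDS annotation.** Sequences with four runs of
   three or more guanines separated by short loops can fold into
   G-quadruplex (G4) DNA. The package detects them two ways and merges hits
   into disjoint "potential non-B DNA-forming sequence" (PONDS) intervals.
2. **Somatic mutation burden at PONDS.** Tumor mutation tables are reduced
   to per-sample totals and a per-sample *percent of mutations at G4*;
   samples grouped by the protein domain of their *TOP1* mutation are
   compared against random control sets with Wilcoxon rank-sum tests.
3. **Fluctuation-assay rates.** Mutant counts over parallel cultures yield
   mutation/recombination rates by the Lea–Coulson method of the median.

All randomized steps take explicit seeds; reruns are byte-identical.

## G4 detection

### Canonical scan

The canonical motif is `G{r,}(N{a,b}G{r,}){3}` with run length `r = 3` and
loop bounds `a = 1`, `b = 7` by default. Matching uses standard greedy,
leftmost, non-overlapping regular-expression semantics — the community
default for this pattern and directly checkable against any independent
regex engine. The reverse strand is scanned on the reverse complement and
reported in forward coordinates with strand `-`. Coordinates are 0-based
half-open everywhere (BED convention). Matching is case-insensitive; `N`
never extends a guanine run, but loops may contain any base including `N`
and `G` (conservative ambiguity handling).

Long chromosomes are scanned sequentially in chunks of roughly `window` nt
(default 500 kb). Chunk boundaries are placed only inside stretches of more
than `b` consecutive non-G bases on the scanned strand: no motif — and no
greedy non-overlapping match chain — can cross such a stretch, so chunked
output is provably identical to a whole-chromosome scan. This sequential
design replaces any need for parallel scanning at the scales the package
targets.

### QGRS enumeration and G-score

A QGRS candidate is four *equal-size* guanine groups (`g` tetrads each,
`g >= 3` by default), each a contiguous sub-run of a maximal G run, with
loop lengths `l1, l2, l3` in [0, 10] and total span at most 44 nt (the
parameter set used for the published oligo table). Enumeration is
exhaustive and therefore restricted to oligo-scale sequences (10 kb guard,
overridable).

Each candidate gets an integer G-score implementing the three QGRS
principles — more stacked tetrads beat fewer; shorter loops beat longer;
even loops beat uneven loops at the same total:

$$ s(g, l_1, l_2, l_3) = 2\,g_{max}(g - 1) \;-\;
   \left\lfloor \tfrac{2(l_1+l_2+l_3) + |l_1-l_2| + |l_1-l_3| + |l_2-l_3|}{3}
   \right\rfloor, \qquad g_{max} = \lfloor L/2 \rfloor - 1 $$

with `L` the maximum-length parameter. The tetrad term counts
tetrad–tetrad stacking interfaces (`g − 1`); the loop penalty is twice the
mean loop length plus the mean pairwise loop asymmetry, a weighting chosen
so the score is monotone non-increasing in every individual loop length
(growing one loop can reduce the asymmetry term by at most 2/3 per unit,
less than the 2·(1/3) gained by the mean-length term). The scale constant
`g_max` ties the score to the length budget; it is calibrated on the single
published worked example available to this analysis: the 45-nt
switch-region oligo SμG must score 70 at `L = 44`, which the formula
reproduces by computation. Scores from different `L` values are therefore
not comparable — the published figure of merit is defined at `L = 44`.

Per overlapping family, one best motif is reported by greedy selection in
descending score (ties: leftmost start, then shortest span), mirroring
QGRS-style reporting.

### PONDS intervals

Motif hits from both strands and either detector are merged
(interval union) into maximal disjoint PONDS intervals, because the
downstream question — does a mutation fall in G4-capable sequence? — is
strand-blind and needs a well-defined denominator. Merged intervals keep
the best contained G-score and a strand label (`.` when both strands
contribute).

## Cohort analysis

### Input dialect and filters

The reader consumes a tab-separated mutation table in the COSMIC
mutant-export dialect (configurable column map, so fixtures need not
replicate the full export schema). Filters, in order:

* keep only rows whose genome-wide-screen flag is `y`;
* drop rows with unparseable coordinates (counted in a message);
* collapse duplicate identical rows within a sample (same coordinates and
  protein change) — double-counted export rows would inflate burden; a flag
  restores literal counting;
* remove entirely any sample whose sample code is associated with more than
  one tumor type (ambiguous identity).

Coordinates stay 1-based inclusive at the boundary (as exported) and are
converted to 0-based half-open at first internal use. Substitutions and
deletions intersect PONDS over their full reported span; the insertion
dialect `start = end + 1` is treated as its 2-bp flanking interval. A
mutation counts once regardless of span ("percent mutations", not percent
bases).

### TOP1 domain groups

Protein changes are parsed from HGVS-like strings (`p.Y723F`, `p.W736*`,
`p.G12fs`, with unparseable input a value, never an error) and classified:
nonsense/frameshift → **Stop** anywhere in the coding region; missense →
the domain containing the residue (N-Ter 1–214, Core 215–634, Linker
635–711, C-Ter 712–765); synonymous/other → none. When one sample carries
classifiable changes in several groups it is assigned once, by precedence
Stop > C-Ter > Linker > Core > N-Ter — the classes most likely to
compromise catalytic function win, consistent with the analysis's focus on
catalytic-defect groups; affected samples are reported. This rule is a
package design choice: unique assignment is required, but no published rule
exists for multi-mutation samples.

### Control sets and comparisons

* **Ran**: `n = 300` samples drawn uniformly without replacement, seeded,
  after sorting by sample id (so selection is invariant to input row
  order).
* **Ran_H**: a seeded uniform pool of up to 1,500 samples from those with
  at least 400 mutations, code-deduplicated, then `n = 300` drawn from the
  pool — the two-stage construction of the high-burden control.

Group comparisons pool member groups by concatenating their per-sample
values and run a single two-sided Wilcoxon rank-sum test: exact
enumeration when both groups are tie-free and no larger than
`exact_max_n = 25` (a feasible enumeration bound), otherwise the normal
approximation with midranks, tie-corrected variance and continuity
correction. Two-sided p-values are the conservative choice where sidedness
is unspecified. No multiple-testing correction is applied by default,
matching per-comparison reporting; `holm = TRUE` adds Holm adjustment.
At size 8 vs 8 the corrected normal approximation tracks the discrete exact
distribution to within about 0.011 in the worst case — an intrinsic
property of the approximation, reflected in the test suite's tolerance.

## Fluctuation assays

For mutant counts $r_1,\dots,r_C$ over $C$ cultures (the package expects
the 12–36 used in practice, and at least 2), the Lea–Coulson method of the
median solves $\tilde r/m - \ln m = 1.24$ for the expected number of
mutational events per culture $m$, by bracketing bisection to relative
tolerance $10^{-9}$ (the equation's left side is strictly decreasing in
$m$, so the root is unique; the residual at the returned root is below
$10^{-8}(1+\tilde r)$). The median estimator needs a median of at least one
mutant: when at least half the cultures have zero mutants (sample median
below 1) the zero-fraction estimator $m = -\ln p_0$ is used instead and
flagged. The rate is $m/N_t$, with $N_t$ the viable cells per culture
(mean of the supplied total-CFU measurements). The 95% CI uses the
large-sample approximation $\sigma_{\ln m} = 1.225\,m^{-0.315}/\sqrt{C}$,
exponentiated and scaled by $N_t$ — a standard documented approximation
whose coverage the test suite verifies by simulation (≥ 90% at
$m = 2$, $C = 24$) rather than a claim about any particular historical
implementation. Two rates are reported as significantly different exactly
when their 95% CIs do not overlap.

## Synthetic data: what it emulates, and what it does not

The generators provide ground truth for every stage:

* `make_genome()` builds random background sequence in which every G run
  and C run of 3+ is broken (so neither strand can form a spurious
  canonical motif), implants a configurable number of canonical-motif
  copies — half as reverse complements — at well-separated recorded
  coordinates with a one-base T buffer, and *verifies* that the canonical
  scanner reproduces the implant coordinates exactly before returning.
* `make_cohort()` draws per-sample totals from a negative binomial
  (background median 79, dispersion 1.3 — overdispersed to emulate the
  heavy right tail of real per-sample totals; mutant groups get a 12-fold
  mean multiplier). Each mutation lands in PONDS with probability
  $f p / (f p + (1-p))$, where $p$ is the genome's PONDS base fraction and
  $f$ the group's enrichment factor (default 5 for C-Ter and Stop, 1
  elsewhere — the qualitative structure under study), uniformly within the
  chosen stratum. TOP1-mutant samples carry one TOP1 record whose protein
  change is synthesized to match the planted group, exercising the
  parser's full grammar. Truth files carry group, total and in-PONDS count
  per sample, sufficient to recompute every downstream statistic.
* `simulate_luria_delbruck()` draws Poisson(m) mutational events per
  culture; an event with $d$ doublings still to go (probability
  $2^{-(d+1)}$, the uniform-over-cell-divisions construction) contributes
  a clone of $2^d$ mutant cells, truncated at $N_t$.

What the generators do **not** emulate: trinucleotide mutational
signatures, chromosome-scale genome organization, tumor-type covariates,
copy-number effects, sequencing error, or phenotypic lag and plating
efficiency in the fluctuation assay. Passing tests therefore demonstrate
the pipeline's statistical machinery and bookkeeping on data with known
structure — not robustness to the full messiness of real tumor genomes.

On the null-calibration design: the enrichment-recovery check runs the
cohort exactly as specified (12× totals, 5× enrichment) and must detect it;
the companion calibration runs with *both* the enrichment and the count
multiplier at 1. The multiplier must be neutralized in the calibration arm
because the rank-sum null requires identical distributions: mutant samples
with 12-fold more mutations have much tighter percent-at-G4 distributions
than background samples (a binomial proportion over ~950 versus ~79
draws, the latter with a large atom at exactly zero), so their rank-sum
p-values are non-uniform even with no enrichment whatsoever. With
identical generating distributions, deviation from uniformity would
indicate a defect in the placement or intersection machinery — which is
what the calibration is for.

## Numerical and degenerate-input choices

* Coordinates: 0-based half-open internally and in BED; COSMIC input is
  1-based inclusive and converted at first use.
* Empty sequence → empty motif table (not an error); empty record list →
  empty profile table; a sample with zero records has no percent-at-G4
  (absent, not 0).
* Chromosomes absent from the PONDS index count as non-overlapping
  (reported once per chromosome).
* G-score ties in best-motif selection break by leftmost start, then
  shortest span — deterministic output.
* `select_ran()`/`select_ran_high()` sort ids before sampling; the seed is
  part of the output manifest in `run_pipeline()`.
* All generator draws happen under a temporarily-set seed that restores
  the caller's RNG state.

## Problem sizes in the test suite

The suite exercises: 1,000 random 200-nt sequences against an independent
regex engine; a 100-kb genome with 25–80 implanted motifs; cohorts of 300
background + 30 mutant samples across 100 seeds for both the enrichment
and calibration arms; 500 simulated fluctuation experiments of 24 cultures
at $m = 2$. These sizes give stable pass/fail behavior for the stochastic
checks while keeping a full run around a minute on one core.

## Known limitations

* The G-score is this package's own calibrated integer scheme; it orders
  candidates by the QGRS principles and reproduces the published worked
  example, but is not guaranteed to equal any external tool's score on
  arbitrary input.
* Exhaustive QGRS enumeration is quadratic-ish in guanine density and
  gated to ≤ 10 kb; genome-scale annotation should use canonical mode.
* Consequence classification is string-based (no transcript model); only
  one gene's domain map is applied per run.
* The fluctuation CI is a large-C approximation; for very small culture
  counts the CI-overlap rule is conservative.
* Indels spanning a PONDS boundary count as overlapping (full-span
  intersection) — the handling of such rows in historical datasets is
  unknowable from published methods.
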