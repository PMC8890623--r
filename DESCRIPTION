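Package: g4burden
Title: Somatic Mutation Burden at G-Quadruplex Motifs and Fluctuation-Assay
    Rate Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects G-quadruplex-capable sequences (canonical G4 pattern and
    QGRS-style enumeration with integer G-scoring), merges motif hits into
    potential non-B DNA-forming sequence (PONDS) intervals, intersects somatic
    mutation tables in the COSMIC mutant-export dialect with those intervals,
    and compares per-sample mutation burden and percent-of-mutations-at-G4
    between TOP1 domain-mutant groups and random control sets using Wilcoxon
    rank-sum tests. Also estimates mutation and recombination rates from
    Luria-Delbruck fluctuation-assay colony counts by the Lea-Coulson method
    of the median with 95 percent confidence intervals, and ships a
    ground-truthed synthetic-data generator (genomes with implanted motifs,
    cohorts with planted domain-group structure and G4 enrichment, simulated
    fluctuation experiments) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
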