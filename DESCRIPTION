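Package: dgscreen
Title: Integrative Driver-Gene Screening from Copy Number, Expression,
    RNAi Dependency and Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies candidate cancer driver genes by intersecting four
    evidence layers over a tumor cohort: recurrent copy-number alterations
    scored with a GISTIC-style G statistic and permutation false-discovery
    rates; per-gene concordance of copy-number and expression change
    (equally directed abnormality tested by exact Wilcoxon signed-rank);
    lineage-specific gene essentiality from pooled shRNA screens scored by
    Kolmogorov-Smirnov rank enrichment with permutation p-values; and
    Kaplan-Meier / Cox proportional-hazards survival screening. Ships a
    synthetic-cohort simulator with planted ground truth (focal amplicons
    and deletions, arm-level events, dosage-driven expression, essential
    genes, prognostic genes) so the whole pipeline is testable end to end,
    plus readers and writers for SEG, GCT v1.2, BED and TSV interchange
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
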