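#!/usr/bin/env Rscript
# Stage 6: evidence intersection and candidate ranking.
#
# Joins the four evidence layers by gene symbol, sets the five flags
# (in peak, concordant, prognostic univariate/multivariate, vulnerable),
# and ranks by evidence count with peak-q / vulnerability-q tie-breaks.

suppressPackageStartupMessages(library(dgscreen))

dir.create("results/rank", recursive = TRUE, showWarnings = FALSE)

peaks <- read_tsv_table("results/cna/peaks.tsv")
conc <- read_tsv_table("results/concordance/concordance.tsv")
forest <- read_tsv_table("results/survival/survival_forest.tsv")
vuln <- read_tsv_table("results/vulnerability/lineage_essential.tsv")
annotation <- read_tsv_table("results/data/annotation.tsv")

surv <- list(univariate = forest[forest$model == "univariate", ],
             multivariate = {
               m <- forest[forest$model == "multivariate", ]
               if (nrow(m)) m else NULL
             })
candidates <- intersect_evidence(peaks, conc, surv, vuln,
                                 annotation = annotation)
write_tsv_table(candidates, "results/rank/candidates.tsv")

top <- candidates[1, ]
message(sprintf("ranked %d genes; top candidate: %s (%s), evidence %d/5",
                nrow(candidates), top$gene, top$locus, top$evidence_count))
print(utils::head(candidates[c("gene", "locus", "in_peak", "concordant",
                               "prognostic_univariate",
                               "prognostic_multivariate", "vulnerable",
                               "evidence_count")], 5))
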