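#!/usr/bin/env Rscript
# Stage 3: copy-number / expression concordance.
#
# Tests every annotated gene for equally directed abnormality: exact
# Wilcoxon signed-rank on gene-level copy number (vs diploid zero) and
# on tumor-minus-reference expression ratios, both at p < 1e-6, gated on
# agreeing directions (copy-number direction needs |median| >= 0.1 log2).
# Produces the per-gene table and the per-peak candidate-target report.

suppressPackageStartupMessages(library(dgscreen))

dir.create("results/concordance", recursive = TRUE, showWarnings = FALSE)

segs <- read_seg("results/data/tumor_cn.seg")
grid <- read_tsv_table("results/data/marker_grid.tsv")
mm <- segments_to_markers(segs, grid)
annotation <- read_tsv_table("results/data/annotation.tsv")
ev <- read_gct("results/data/expression.gct")
roles <- read_tsv_table("results/data/expression_samples.tsv")
expr <- expression_matrix(ev, roles$sample[roles$role == "reference_normal"])

conc <- concordance_screen(mm, expr, annotation)
peaks <- read_tsv_table("results/cna/peaks.tsv")
cand <- candidate_targets(peaks, conc)

write_tsv_table(conc, "results/concordance/concordance.tsv")
write_tsv_table(cand, "results/concordance/candidate_targets.tsv")

dosage <- read_tsv_table("results/data/truth_dosage_genes.tsv")
message(sprintf("%d / %d genes concordant; %d / %d planted dosage genes flagged",
                sum(conc$concordant), nrow(conc),
                sum(conc$concordant[match(dosage$gene, conc$gene)]),
                nrow(dosage)))
message(sprintf("candidate targets across %d peaks: %d",
                nrow(cand), sum(cand$n_candidates)))
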