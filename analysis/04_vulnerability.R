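#!/usr/bin/env Rscript
# Stage 4: shRNA-screen vulnerability and lineage-specific essentiality.
#
# Scores every gene in every cell line by KS top-enrichment of its
# hairpins in the depletion ranking (-log10 permutation p, B = 1000),
# then contrasts esophagus-lineage lines against all others by Welch
# t-test with BH correction at q <= 0.1.

suppressPackageStartupMessages(library(dgscreen))

seed <- 20260926L %% 1000L
dir.create("results/vulnerability", recursive = TRUE, showWarnings = FALSE)

scores <- read_gct("results/data/screen.gct")
map <- read_tsv_table("results/data/shrna_map.tsv")
lin <- read_tsv_table("results/data/cell_lineages.tsv")
screen <- screen_matrix(scores, map, setNames(lin$lineage, lin$cell_line))

vt <- vulnerability_table(screen, B = 1000L, seed = seed + 2L)
ls <- lineage_specific_genes(vt, screen$lineage, "esophagus",
                             q_cutoff = 0.1,
                             annotation = read_tsv_table(
                               "results/data/annotation.tsv"))

write_gct(vt$v, "results/vulnerability/vulnerability_scores.gct")
write_tsv_table(ls, "results/vulnerability/lineage_essential.tsv")

truth <- read_tsv_table("results/data/truth_essential_genes.tsv")
called <- ls$gene[ls$significant]
message(sprintf("lineage-essential at q <= 0.1: %d genes (%s)",
                length(called), paste(called, collapse = ", ")))
message(sprintf("planted recovered: %d / %d; false positives: %d",
                sum(truth$gene %in% called), nrow(truth),
                length(setdiff(called, truth$gene))))
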