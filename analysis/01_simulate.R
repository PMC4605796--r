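#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort and write it in interchange formats.
#
# Generates the default synthetic cohort -- 60 tumors / 3 reference
# normals on a 5 x 1000-marker grid with three planted focal events, two
# arm-level events, dosage-driven expression, a pooled shRNA screen
# (100 lines, 9 esophagus) and expression-linked survival -- and writes
# SEG / GCT / TSV inputs under results/data/ for the later stages.

suppressPackageStartupMessages(library(dgscreen))

seed <- 20260926L %% 1000L   # fixed workflow seed
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)
scr <- simulate_screen(cfg)

write_seg(cohort$segments, "results/data/tumor_cn.seg")
write_tsv_table(cohort$tumor_cn$markers, "results/data/marker_grid.tsv")
write_gct(cohort$expression$values, "results/data/expression.gct")
write_tsv_table(data.frame(sample = colnames(cohort$expression$values),
                           role = ifelse(colnames(cohort$expression$values)
                                         %in% cohort$expression$ref_ids,
                                         "reference_normal", "tumor")),
                "results/data/expression_samples.tsv")
write_tsv_table(cohort$annotation, "results/data/annotation.tsv")
write_tsv_table(cohort$clinical, "results/data/clinical.tsv")
write_gct(scr$screen$scores, "results/data/screen.gct")
write_tsv_table(scr$screen$map, "results/data/shrna_map.tsv")
write_tsv_table(data.frame(cell_line = names(scr$screen$lineage),
                           lineage = unname(scr$screen$lineage)),
                "results/data/cell_lineages.tsv")
write_tsv_table(cohort$truth$planted_driver_regions,
                "results/data/truth_regions.tsv")
write_tsv_table(cohort$truth$planted_dosage_genes,
                "results/data/truth_dosage_genes.tsv")
write_tsv_table(cohort$truth$planted_lineage_essential_genes,
                "results/data/truth_essential_genes.tsv")

message(sprintf(
  "simulated %d tumors / %d normals, %d markers, %d genes, %d cell lines (seed %d)",
  cfg$n_tumors, cfg$n_normals, nrow(cohort$tumor_cn$markers),
  cfg$n_genes, cfg$screen$n_cell_lines, seed))
message("planted: ", nrow(cohort$truth$planted_driver_regions),
        " focal regions, ", nrow(cohort$truth$planted_dosage_genes),
        " dosage genes, ",
        nrow(cohort$truth$planted_lineage_essential_genes),
        " lineage-essential genes, driver gene ",
        cohort$truth$planted_prognostic_genes$gene[1])
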