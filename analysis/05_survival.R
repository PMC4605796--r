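#!/usr/bin/env Rscript
# Stage 5: survival screen over the genes in recurrence peaks.
#
# Dichotomizes each peak gene's expression at the upper-quartile cutoff,
# fits univariate Cox models (administrative censoring at 60 months,
# Efron ties), and feeds every variable with univariate p < 0.05 into a
# single multivariate model. Also writes the Kaplan-Meier step function
# for the planted driver's high/low groups.

suppressPackageStartupMessages(library(dgscreen))

dir.create("results/survival", recursive = TRUE, showWarnings = FALSE)

clinical <- read_tsv_table("results/data/clinical.tsv")
ev <- read_gct("results/data/expression.gct")
roles <- read_tsv_table("results/data/expression_samples.tsv")
expr <- expression_matrix(ev, roles$sample[roles$role == "reference_normal"])
peaks <- read_tsv_table("results/cna/peaks.tsv")
peak_genes <- unique(unlist(strsplit(peaks$genes, ",")))
peak_genes <- peak_genes[nzchar(peak_genes)]

scr <- univariate_screen(clinical, expr, genes = peak_genes,
                         covariates = "node_positive")
forest <- rbind(scr$univariate, scr$multivariate)
write_tsv_table(forest, "results/survival/survival_forest.tsv")

driver <- read_tsv_table("results/data/truth_dosage_genes.tsv")$gene[5]
grp <- dichotomize_expression(ev[driver, clinical$id])
km_high <- km_estimate(clinical$time_months[grp == "high"],
                       clinical$event[grp == "high"])
km_low <- km_estimate(clinical$time_months[grp == "low"],
                      clinical$event[grp == "low"])
km_high$group <- "high"; km_low$group <- "low"
write_tsv_table(rbind(km_high, km_low), "results/survival/km_driver.tsv")
lr <- logrank_test(clinical$time_months, clinical$event, grp)

sig <- scr$univariate$variable[!is.na(scr$univariate$p) &
                                 scr$univariate$p < 0.05]
message(sprintf("univariate p < 0.05: %d of %d screened variables",
                length(sig), nrow(scr$univariate)))
message(sprintf("driver %s: log-rank p = %.3g for high vs low expression",
                driver, lr$p_value))
if (!is.null(scr$multivariate))
  message(sprintf("multivariate p < 0.05: %s",
                  paste(scr$multivariate$variable[scr$multivariate$p < 0.05],
                        collapse = ", ")))
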