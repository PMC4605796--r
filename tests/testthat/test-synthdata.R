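test_that("zero-noise planted events force exact copy-number values", {
  cfg <- small_sim_config(marker_noise_sd = 0, expression_noise_sd = 0,
                          focal_events = list(list(
                            chrom = 1L, start_marker = 21L, end_marker = 30L,
                            direction = "amp", amplitude_mean = 1,
                            amplitude_sd = 0, prevalence = 1)))
  co <- simulate_cohort(cfg)
  span <- which(co$tumor_cn$markers$chrom == 1 &
                  co$tumor_cn$markers$pos >= 21 * 10000 &
                  co$tumor_cn$markers$pos <= 30 * 10000)
  expect_true(all(co$tumor_cn$values[span, ] == 1))
  expect_true(all(co$tumor_cn$values[-span, ] == 0))
  expect_true(all(co$normal_cn$values == 0))
  # dosage gene expression tracks CN exactly at zero noise (beta = 1)
  er <- expression_ratio("G0005", co$expression)
  cn <- gene_copy_values("G0005", co$tumor_cn, co$annotation)
  expect_equal(unname(er), unname(cn[co$expression$tumor_ids]))
})

test_that("identical config and seed reproduce identical cohorts and screens", {
  a <- simulate_cohort(small_sim_config(seed = 99L))
  b <- simulate_cohort(small_sim_config(seed = 99L))
  expect_identical(a$tumor_cn$values, b$tumor_cn$values)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$segments, b$segments)
  sa <- simulate_screen(small_sim_config(seed = 99L))
  sb <- simulate_screen(small_sim_config(seed = 99L))
  expect_identical(sa$screen$scores, sb$screen$scores)
  # a different seed moves the data
  expect_false(identical(
    a$tumor_cn$values,
    simulate_cohort(small_sim_config(seed = 100L))$tumor_cn$values))
})

test_that("event carriage is Bernoulli at the configured prevalence", {
  base <- small_sim_config(
    n_chromosomes = 1L, markers_per_chromosome = 20L, centromere_index = 10L,
    n_tumors = 100L, n_genes = 4L, marker_noise_sd = 0,
    focal_events = list(list(chrom = 1L, start_marker = 5L, end_marker = 8L,
                             direction = "amp", amplitude_mean = 1,
                             amplitude_sd = 0, prevalence = 0.8)),
    dosage_genes = data.frame(gene = "G0001", beta = 1),
    screen = list(n_cell_lines = 5L, n_lineage = 2L, shrnas_per_gene = 2L,
                  essential_genes = data.frame(gene = "G0001",
                                               lineage_specific = TRUE,
                                               effect_size = 1),
                  screen_noise_sd = 1),
    survival = list(baseline_hazard = 0.04,
                    prognostic_genes = data.frame(gene = "G0001",
                                                  log_hr = 1),
                    high_quantile = 0.75, censoring_window = 120,
                    admin_censor_months = 60))
  carriers <- vapply(1:50, function(s) {
    cfg <- base
    cfg$seed <- as.integer(s)
    length(simulate_cohort(cfg)$truth$focal_carriers[[1]]$carriers)
  }, numeric(1))
  total <- sum(carriers)
  ci <- qbinom(c(0.005, 0.995), 50L * 100L, 0.8)
  expect_gte(total, ci[1]); expect_lte(total, ci[2])
})

test_that("screen scores are exact at zero noise and essential hairpins rank first", {
  cfg <- small_sim_config(screen = list(
    n_cell_lines = 20L, n_lineage = 5L, shrnas_per_gene = 5L,
    essential_genes = data.frame(gene = "G0005", lineage_specific = TRUE,
                                 effect_size = 2),
    screen_noise_sd = 0))
  scr <- simulate_screen(cfg)$screen
  ess <- scr$map$shrna[scr$map$gene == "G0005"]
  lin <- names(scr$lineage)[scr$lineage == "esophagus"]
  oth <- setdiff(colnames(scr$scores), lin)
  expect_true(all(scr$scores[ess, lin] == -2))
  expect_true(all(scr$scores[, oth] == 0))
  for (cl in lin)
    expect_setequal(head(rank_shrnas(scr, cl), 5), ess)
})

test_that("essential-gene hairpins concentrate at the top under realistic noise", {
  below_mid <- vapply(1:100, function(s) {
    cfg <- small_sim_config(
      seed = s, n_genes = 50L,
      screen = list(n_cell_lines = 12L, n_lineage = 4L, shrnas_per_gene = 5L,
                    essential_genes = data.frame(gene = "G0005",
                                                 lineage_specific = TRUE,
                                                 effect_size = 1.5),
                    screen_noise_sd = 1))
    scr <- simulate_screen(cfg)$screen
    lin <- names(scr$lineage)[scr$lineage == "esophagus"]
    ranks <- vapply(lin, function(cl)
      mean(match(scr$map$shrna[scr$map$gene == "G0005"],
                 rank_shrnas(scr, cl))), numeric(1))
    mean(ranks) < (nrow(scr$scores) + 1) / 2
  }, logical(1))
  expect_gte(mean(below_mid), 0.95)
})

test_that("zero-noise segments round-trip through the marker grid exactly", {
  cfg <- small_sim_config(marker_noise_sd = 0)
  co <- simulate_cohort(cfg)
  # piecewise-constant profiles compress into few segments
  expect_lt(nrow(co$segments), 10L * cfg$n_tumors)
  back <- segments_to_markers(co$segments, co$tumor_cn$markers,
                              sample_ids = co$tumor_cn$sample_ids)
  expect_equal(back$values, co$tumor_cn$values)
})

test_that("impossible configurations are rejected up front", {
  expect_error(small_sim_config(focal_events = list(
    list(chrom = 1L, start_marker = 10L, end_marker = 30L, direction = "amp",
         amplitude_mean = 1, amplitude_sd = 0, prevalence = 0.5),
    list(chrom = 1L, start_marker = 25L, end_marker = 40L, direction = "del",
         amplitude_mean = 1, amplitude_sd = 0, prevalence = 0.5))),
    "opposite directions")
  expect_error(small_sim_config(screen = list(
    n_cell_lines = 5L, n_lineage = 9L, shrnas_per_gene = 2L,
    essential_genes = data.frame(gene = "G0001", lineage_specific = TRUE,
                                 effect_size = 1),
    screen_noise_sd = 1)), "n_lineage")
  expect_error(small_sim_config(markers_per_gene = 3L), "multiple")
})
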