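ann3 <- data.frame(gene = c("GA", "GB"), chromosome = c(1L, 1L),
                   start = c(150L, 1800L), end = c(420L, 1900L))
mm3 <- marker_matrix(data.frame(chrom = 1L, pos = c(200L, 300L, 400L, 1000L)),
                     matrix(c(0.2, 0.4, 0.6, 0.3), 4, 1,
                            dimnames = list(NULL, "T1")))

test_that("gene copy number is the marker-span mean with nearest fallback", {
  expect_equal(unname(gene_copy_values("GA", mm3, ann3)), 0.4)
  # GB overlaps no marker; nearest on the chromosome is pos 1000 (0.3)
  expect_equal(unname(gene_copy_values("GB", mm3, ann3)), 0.3)
  # distance tie prefers the left marker
  annT <- data.frame(gene = "GT", chromosome = 1L, start = 590L, end = 610L)
  mmT <- marker_matrix(data.frame(chrom = 1L, pos = c(500L, 700L)),
                       matrix(c(0.1, 0.9), 2, 1,
                              dimnames = list(NULL, "T1")))
  expect_equal(unname(gene_copy_values("GT", mmT, annT)), 0.1)
  annX <- data.frame(gene = "GX", chromosome = 9L, start = 1L, end = 10L)
  expect_error(gene_copy_values("GX", mm3, annX), "absent")
  expect_error(gene_copy_values("NOPE", mm3, ann3), "not found")
})

test_that("expression ratios subtract the reference-normal mean", {
  ev <- matrix(c(5, 4, 4, 4), 1, 4,
               dimnames = list("GA", c("T1", "N1", "N2", "N3")))
  ex <- expression_matrix(ev, ref_ids = c("N1", "N2", "N3"))
  expect_equal(unname(expression_ratio("GA", ex)), 1)
  ev2 <- ev; ev2[1, 1] <- 4
  ex2 <- expression_matrix(ev2, ref_ids = c("N1", "N2", "N3"))
  expect_equal(unname(expression_ratio("GA", ex2)), 0)
  expect_error(expression_ratio("NOPE", ex), "not found")
})

test_that("equally directed abnormality needs both tails and agreeing directions", {
  # 30 tumors, uniform gain and overexpression: both exact p at the floor
  r <- concordance_test(rep(0.5, 30), rep(1.0, 30))
  expect_true(r$concordant)
  expect_equal(r$cn_p, 2 * 2^-30)
  expect_equal(r$expr_p, 2 * 2^-30)
  expect_identical(c(r$cn_direction, r$expr_direction), c("+", "+"))
  # symmetric expression kills the expression tail
  r2 <- concordance_test(rep(0.5, 30), rep(c(1, -1), 15))
  expect_false(r2$concordant)
  expect_equal(r2$expr_p, 1)
  # opposite directions are never concordant
  r3 <- concordance_test(rep(0.5, 30), rep(-1, 30))
  expect_false(r3$concordant)
  # degenerate all-zero input: p = 1, not concordant
  r4 <- concordance_test(rep(0, 30), rep(0, 30))
  expect_false(r4$concordant)
  expect_equal(r4$cn_p, 1)
  # sub-0.1 copy-number medians have no direction
  r5 <- concordance_test(rep(0.05, 30), rep(1, 30))
  expect_identical(r5$cn_direction, "0")
  expect_false(r5$concordant)
  expect_warning(concordance_test(rep(0.5, 10), rep(1, 10)), "cannot reach")
})

test_that("negating both layers flips directions but preserves concordance", {
  set.seed(17)
  for (rep in 1:10) {
    cn <- rnorm(30, mean = sample(c(-0.5, 0, 0.5), 1), sd = 0.3)
    er <- rnorm(30, mean = sample(c(-1, 0, 1), 1), sd = 0.5)
    a <- concordance_test(cn, er, warn_small = FALSE)
    b <- concordance_test(-cn, -er, warn_small = FALSE)
    expect_identical(a$concordant, b$concordant)
    flip <- c("+" = "-", "-" = "+", "0" = "0")
    expect_identical(unname(flip[a$cn_direction]), b$cn_direction)
    expect_identical(unname(flip[a$expr_direction]), b$expr_direction)
  }
})

test_that("zero-noise dosage genes reproduce planted amplitudes through both layers", {
  cfg <- small_sim_config(marker_noise_sd = 0, expression_noise_sd = 0,
                          focal_events = list(list(
                            chrom = 1L, start_marker = 21L, end_marker = 30L,
                            direction = "amp", amplitude_mean = 1,
                            amplitude_sd = 0, prevalence = 1)))
  co <- simulate_cohort(cfg)
  cn <- gene_copy_values("G0005", co$tumor_cn, co$annotation)
  expect_true(all(cn == 1))
  expect_equal(unname(expression_ratio("G0005", co$expression)),
               unname(cn[co$expression$tumor_ids]))
})

test_that("candidate targets are the concordant genes matching each peak's direction", {
  peaks <- data.frame(chromosome = 1L, start = 1L, end = 10L,
                      direction = "amplification", peak_pos = 5L,
                      max_G = 1, min_q = 0.01, frequency = 0.8,
                      n_genes = 2L, genes = "GA,GB")
  res <- data.frame(gene = c("GA", "GB"),
                    cn_p = c(1e-9, 1e-9), expr_p = c(1e-9, 0.5),
                    cn_direction = c("+", "+"), expr_direction = c("+", "0"),
                    concordant = c(TRUE, FALSE))
  ct <- candidate_targets(peaks, res)
  expect_equal(ct$candidate_targets, "GA")
  expect_equal(ct$n_candidates, 1L)
  expect_equal(ct$n_genes, 2L)
  # all genes failing concordance: empty candidates, inventory unchanged
  res$concordant <- FALSE
  ct2 <- candidate_targets(peaks, res)
  expect_equal(ct2$candidate_targets, "")
  expect_equal(ct2$n_genes, 2L)
})
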