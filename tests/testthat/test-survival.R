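test_that("quantile dichotomization splits cohorts as expected", {
  g <- dichotomize_expression(1:100)
  expect_equal(sum(g == "high"), 25L)
  expect_equal(table(dichotomize_expression(1:10, quantile = 0.5))[["high"]],
               5L)
  # an 85-patient cohort at the default splits 64 low / 21 high;
  # a 60/25 split needs a cutoff near the 0.706 quantile
  g85 <- dichotomize_expression(1:85)
  expect_equal(as.vector(table(g85)), c(64L, 21L))
  g85b <- dichotomize_expression(1:85, quantile = 0.706)
  expect_equal(as.vector(table(g85b)), c(60L, 25L))
  expect_error(dichotomize_expression(rep(3, 10)), "constant")
})

test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)
  none <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  set.seed(12)
  time <- round(rexp(20, 0.1), 1) + 0.1
  event <- rbinom(20, 1, 0.7)
  km2 <- km_estimate(time, event)
  oracle <- brute_km(time, event)
  expect_equal(km2$surv[km2$n_event > 0], oracle$surv)
  # nonincreasing step function
  expect_true(all(diff(km2$surv) <= 1e-12))
})

test_that("log-rank test separates hazards and is label-symmetric", {
  t0 <- c(1, 2, 3, 4, 5); e0 <- c(1, 0, 1, 1, 0)
  same <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  sep <- logrank_test(c(rep(1, 20), rep(100, 20)),
                      c(rep(1, 20), rep(0, 20)),
                      rep(c("a", "b"), each = 20))
  expect_lt(sep$p_value, 0.001)
  expect_identical(sep$direction, "+")
  set.seed(2)
  tt <- rexp(40, 0.1); ee <- rbinom(40, 1, 0.8)
  gg <- rep(c("a", "b"), 20)
  swapped <- ifelse(gg == "a", "b", "a")
  expect_equal(logrank_test(tt, ee, gg)$p_value,
               logrank_test(tt, ee, swapped)$p_value)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")), "two nonempty")
})

test_that("Cox fits censor administratively, flag pathologies and reject degenerates", {
  set.seed(33)
  n <- 120
  grp <- rbinom(n, 1, 0.5)
  d <- data.frame(time_months = rexp(n, 0.03 * exp(0.7 * grp)),
                  event = 1L, grp = grp)
  fit <- cox_fit(d, "grp", max_follow_up = 60)
  # identical to fitting survival::coxph on manually truncated data
  d2 <- d
  d2$event[d2$time_months > 60] <- 0L
  d2$time_months <- pmin(d2$time_months, 60)
  ref <- survival::coxph(survival::Surv(time_months, event) ~ grp, data = d2)
  expect_equal(fit$hr, unname(exp(coef(ref))))
  expect_equal(fit$n_events, sum(d2$event))
  expect_error(cox_fit(data.frame(time_months = 1:10, event = 1L, z = 1),
                       "z"), "no variation")
  # perfectly collinear covariates flagged, not fatal
  d$grp2 <- d$grp
  fit2 <- cox_fit(d, c("grp", "grp2"))
  expect_true(any(fit2$flag != ""))
  # complete separation flagged, not fatal
  ds <- data.frame(time_months = c(rep(1, 10), rep(50, 10)),
                   event = c(rep(1L, 10), rep(0L, 10)),
                   g = rep(c(1, 0), each = 10))
  fs <- cox_fit(ds, "g")
  expect_true(any(fs$flag != ""))
})

test_that("Cox recovers a known hazard ratio from simulated data", {
  set.seed(41)
  g <- rbinom(500, 1, 0.5)
  d <- data.frame(time_months = rexp(500, 0.03 * ifelse(g == 1, 2, 1)),
                  event = 1L, g = g)
  fit <- cox_fit(d, "g", max_follow_up = 60)
  expect_gt(fit$hr, 1.6); expect_lt(fit$hr, 2.5)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("the univariate filter feeds only significant variables to the multivariate model", {
  cfg <- small_sim_config(n_tumors = 80L, seed = 61L)
  co <- simulate_cohort(cfg)
  # planted prognostic gene plus null genes
  scr <- univariate_screen(co$clinical, co$expression,
                           genes = c("G0005", sprintf("G%04d", 40:59)),
                           covariates = "node_positive")
  expect_true("G0005" %in% scr$selected)
  expect_lt(scr$univariate$p[scr$univariate$variable == "G0005"], 0.05)
  expect_true(all(scr$multivariate$variable %in% scr$selected))
  # survival decoupled from expression: screening only null genes must
  # be able to return an empty selection with the multivariate skipped
  co$clinical$time_months <- rev(co$clinical$time_months)
  co$clinical$event <- rev(co$clinical$event)
  found_empty <- FALSE
  for (gset in list(sprintf("G%04d", 40:42), sprintf("G%04d", 43:45))) {
    s2 <- suppressMessages(
      univariate_screen(co$clinical, co$expression, genes = gset))
    if (!length(s2$selected)) {
      expect_null(s2$multivariate)
      found_empty <- TRUE
      break
    }
  }
  expect_true(found_empty)
})
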