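# Shared fixtures and independent brute-force oracles. Oracles are
# deliberately naive re-derivations (enumeration, running sums, hand
# product-limit) kept separate from the implementation paths they check.

small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    n_chromosomes = 2L, markers_per_chromosome = 200L,
    centromere_index = 100L, n_tumors = 30L, n_normals = 3L,
    n_genes = 80L, markers_per_gene = 5L,
    focal_events = list(list(chrom = 1L, start_marker = 21L,
                             end_marker = 30L, direction = "amp",
                             amplitude_mean = 1, amplitude_sd = 0.1,
                             prevalence = 0.8)),
    arm_events = list(),
    dosage_genes = data.frame(gene = "G0005", beta = 1),
    screen = list(n_cell_lines = 20L, n_lineage = 5L, shrnas_per_gene = 5L,
                  essential_genes = data.frame(gene = "G0005",
                                               lineage_specific = TRUE,
                                               effect_size = 2),
                  screen_noise_sd = 1),
    survival = list(baseline_hazard = 0.04,
                    prognostic_genes = data.frame(gene = "G0005",
                                                  log_hr = 1.2),
                    high_quantile = 0.75, censoring_window = 120,
                    admin_censor_months = 60),
    seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
brute_signed_rank_p <- function(values) {
  v <- values[values != 0]
  n <- length(v)
  stopifnot(n <= 14L)
  r <- rank(abs(v))
  W <- sum(r[v > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- as.numeric(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(Wnull >= W - eps), mean(Wnull <= W + eps)))
}

# KS top-enrichment by evaluating the running sum at every position
brute_ks_stat <- function(N, hits) {
  k <- length(hits)
  run <- 0; best <- 0
  for (pos in seq_len(N)) {
    run <- run + if (pos %in% hits) 1 / k else -1 / (N - k)
    best <- max(best, run)
  }
  best
}

# literal BH step-up definition: q_i = min over j with p_(j) >= p_i of
# m * p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    j <- which(ps >= pi - 1e-15)
    min(1, min(m * ps[j] / j))
  }, numeric(1))
}

# hand product-limit estimator over distinct event times
brute_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    deaths <- sum(time == ts[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# G score by explicit double summation
brute_gscore <- function(x, theta, direction) {
  M <- nrow(x); N <- ncol(x)
  g <- numeric(M)
  for (m in seq_len(M)) {
    acc <- 0
    for (s in seq_len(N))
      acc <- acc + if (direction == "amp") max(0, x[m, s] - theta)
                   else max(0, theta - x[m, s])
    g[m] <- acc / N
  }
  g
}

# does a detected peak of the right direction overlap a planted region?
region_recovered <- function(peaks, region) {
  dir <- if (region$direction == "amp") "amplification" else "deletion"
  any(peaks$direction == dir & peaks$chromosome == region$chrom &
        peaks$start <= region$end & peaks$end >= region$start)
}
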