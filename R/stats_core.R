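# Shared statistical primitives used by every analysis stage. All tests
# return a `dg_test` record: statistic, p-value, direction and a method tag.

new_test_result <- function(statistic, p_value, direction, method_tag) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12,
            direction %in% c("+", "-", "0"))
  structure(
    list(statistic = unname(statistic), p_value = min(1, unname(p_value)),
         direction = direction, method_tag = method_tag),
    class = "dg_test")
}

#' @export
print.dg_test <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %.6g, p = %.4g, direction = %s\n",
              x$method_tag, x$statistic, x$p_value, x$direction))
  invisible(x)
}

# Exact null of the (doubled, integer) signed-rank statistic by the shift
# algorithm: each |value| contributes its doubled midrank with an
# independent fair sign, so the null pmf is built by B(n) half-weight
# convolutions. Handles midrank ties, O(n * sum(weights)) time.
signrank_null_pmf <- function(weights2) {
  S <- sum(weights2)
  p <- numeric(S + 1L)
  p[1L] <- 1
  for (w in weights2) {
    q <- p * 0.5
    q[(w + 1L):(S + 1L)] <- q[(w + 1L):(S + 1L)] + 0.5 * p[1L:(S + 1L - w)]
    p <- q
  }
  p
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Tests whether a vector of paired differences (here: per-tumor log2
#' copy-number values, or tumor-minus-reference expression ratios) is
#' symmetric about zero. Zeros are removed first; ties in the absolute
#' values take midranks. For `n <= exact_max` nonzero values the p-value
#' comes from the exact permutation null of the signed-rank statistic
#' (all 2^n sign assignments, computed by a shift-algorithm convolution,
#' so midrank ties are handled exactly); beyond that a normal
#' approximation with continuity and tie correction is used. Exactness at
#' cohort scale matters because the concordance screen applies a 1e-6
#' threshold that only the exact tail can reach honestly.
#'
#' @param values numeric vector; zeros are dropped before ranking.
#' @param alternative `"two_sided"` (default), `"greater"` (mass above 0)
#'   or `"less"`.
#' @param method `"auto"` (exact up to `exact_max`, else approximate),
#'   `"exact"`, or `"approx"`.
#' @param exact_max largest n handled exactly under `method = "auto"`.
#' @return A `dg_test` with the signed-rank statistic W (sum of positive
#'   ranks), the p-value, and direction = sign of the median of `values`.
#' @examples
#' signed_rank_test(c(0.4, 0.5, 0.3, 0.6, 0.45, 0.52, 0.38, 0.41))
#' @export
signed_rank_test <- function(values,
                             alternative = c("two_sided", "greater", "less"),
                             method = c("auto", "exact", "approx"),
                             exact_max = 100L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(is.numeric(values), all(is.finite(values)))
  v <- values[values != 0]
  n <- length(v)
  if (n == 0L)
    stop("signed-rank test undefined: all values are zero")
  if (n < 6L)
    warning("fewer than 6 nonzero values; p-value resolution is coarse")
  r <- rank(abs(v))
  W <- sum(r[v > 0])
  if (method == "auto") method <- if (n <= exact_max) "exact" else "approx"

  if (method == "exact") {
    w2 <- as.integer(round(2 * r))
    pmf <- signrank_null_pmf(w2)
    s <- as.integer(round(2 * W))
    p_ge <- sum(pmf[(s + 1L):length(pmf)])
    p_le <- sum(pmf[1L:(s + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
    p_ge <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- pnorm((W - mu + 0.5) / sigma)
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_ge, p_le)),
              greater   = p_ge,
              less      = p_le)
  med <- median(values)
  dir <- if (med > 0) "+" else if (med < 0) "-" else "0"
  new_test_result(W, p, dir, paste0("signed_rank_", method))
}

#' One-sided Kolmogorov-Smirnov rank-enrichment statistic
#'
#' Measures how strongly a set of hit ranks (e.g. the ranks of one gene's
#' shRNAs in a cell line's depletion ordering) concentrates at the top of
#' a ranked universe of size N. Walking ranks 1..N, a hit adds 1/k to the
#' hit fraction and a miss adds 1/(N-k) to the miss fraction; the
#' statistic is the maximum of (hit fraction - miss fraction), floored at
#' zero. This is the unweighted enrichment score of gene-set analysis
#' (GSEA with weight 0), one-sided for top enrichment.
#'
#' @param universe_size N, total number of ranked items.
#' @param hit_ranks distinct integer ranks in 1..N, 1 = strongest.
#' @return the statistic, in \[0, 1\].
#' @examples
#' ks_enrichment_stat(100, 1:5)    # perfect top enrichment -> 1
#' ks_enrichment_stat(100, 96:100) # bottom enrichment -> 0
#' @export
ks_enrichment_stat <- function(universe_size, hit_ranks) {
  N <- as.integer(universe_size)
  h <- sort(as.integer(hit_ranks))
  k <- length(h)
  if (k == 0L) stop("hit set is empty")
  if (k >= N) stop("hit set must be a proper subset of the universe")
  if (anyDuplicated(h) > 0L) stop("hit ranks must be distinct")
  if (h[1L] < 1L || h[k] > N) stop("hit ranks must lie in 1..N")
  # the running difference peaks immediately after a hit:
  # after the i-th hit (rank h_i), i hits and h_i - i misses have passed
  i <- seq_len(k)
  max(0, max(i / k - (h - i) / (N - k)))
}

#' Permutation p-value with add-one pseudocount
#'
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so p is never zero and
#' -log10(p) stays finite (the vulnerability score needs this). The null
#' can be supplied as a pre-drawn numeric vector or as a sampler function
#' `f(B)` returning B draws; with a `seed` the draw is deterministic and
#' the caller's RNG state is untouched.
#'
#' @param observed observed statistic.
#' @param null_sampler numeric vector of null draws, or `function(B)`.
#' @param B number of null draws when `null_sampler` is a function.
#' @param seed optional integer seed for the sampler.
#' @return the permutation p-value in (0, 1\].
#' @export
permutation_pvalue <- function(observed, null_sampler, B = NULL, seed = NULL) {
  if (is.function(null_sampler)) {
    B <- as.integer(B)
    if (is.na(B) || B < 1L) stop("B must be a positive integer")
    draws <- with_seed(seed, null_sampler(B))
    if (length(draws) != B)
      stop("null_sampler(B) must return exactly B draws")
  } else {
    draws <- as.numeric(null_sampler)
    B <- length(draws)
    if (B < 1L) stop("null draws are empty")
  }
  (1 + sum(draws >= observed)) / (B + 1)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @return q-values in the input order, monotone nondecreasing in p.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test (Satterthwaite degrees of freedom), two-sided.
#' Used to contrast vulnerability scores between a target lineage and all
#' other cell lines.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values and
#'   jointly nonzero variance.
#' @return a `dg_test`; direction is the sign of `mean(a) - mean(b)`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(new_test_result(0, 1, "0", "welch_t"))
    stop("t-test undefined: zero variance in both groups")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  d <- mean(a) - mean(b)
  dir <- if (ht$statistic == 0) "0" else if (d > 0) "+" else "-"
  new_test_result(ht$statistic, ht$p.value, dir, "welch_t")
}
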