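# Survival screening: Kaplan-Meier curves, log-rank tests, and Cox
# proportional-hazards screening (univariate filter at p < 0.05 feeding
# one multivariate model). Five-year overall survival is framed as
# administrative censoring at 60 months before fitting.

#' Split expression values into high/low groups at a quantile
#'
#' `high` iff the value strictly exceeds the q-th sample quantile
#' (default 0.75, i.e. the top quarter of the cohort is "high").
#'
#' @param values numeric vector, length >= 4, not constant.
#' @param quantile cut quantile in (0, 1).
#' @return factor with levels `low`, `high`, same length as `values`.
#' @export
dichotomize_expression <- function(values, quantile = 0.75) {
  stopifnot(is.numeric(values), length(values) >= 4L,
            quantile > 0, quantile < 1)
  if (max(values) == min(values))
    stop("expression values are constant; high/low split undefined")
  cut_at <- stats::quantile(values, quantile, names = FALSE)
  factor(ifelse(values > cut_at, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time survival times (months, > 0).
#' @param event 1 = death, 0 = censored; censored-at-t subjects count as
#'   at risk at t.
#' @return data.frame of the step function: time, n_risk, n_event,
#'   surv (right-continuous, S(0) = 1 implied).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1L, all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square on 1 degree of freedom.
#'
#' @param time,event survival outcome over all subjects.
#' @param group two-level grouping vector.
#' @return a `dg_test`; direction is "+" when the first group level has
#'   more deaths than expected (higher hazard).
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L || any(tabulate(g, 2L) == 0L))
    stop("log-rank test needs two nonempty groups")
  if (sum(event) < 1L) stop("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- sd$chisq
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  d <- sd$obs[1L] - sd$exp[1L]
  dir <- if (abs(d) < sqrt(.Machine$double.eps)) "0" else if (d > 0) "+" else "-"
  new_test_result(stat, p, dir, "logrank")
}

#' Cox proportional-hazards fit with administrative censoring
#'
#' Applies administrative censoring at `max_follow_up` months first
#' (events beyond it become censored at the horizon -- the "5-year
#' overall survival" framing), then maximises the Efron partial
#' likelihood. Infinite-coefficient / singular fits (complete separation,
#' collinearity) are returned flagged rather than raised; failure to
#' converge is an error.
#'
#' @param data data.frame with columns `time_months`, `event` and the
#'   covariates.
#' @param covariates column names to include.
#' @param ties tie handling, default `"efron"`.
#' @param max_follow_up administrative censoring horizon in months.
#' @param model_tag label stored in the result, e.g. `"univariate"`.
#' @return data.frame, one row per coefficient: variable, term, hr,
#'   ci_low, ci_high, p, n, n_events, flag, model.
#' @export
cox_fit <- function(data, covariates, ties = "efron", max_follow_up = 60,
                    model_tag = "univariate") {
  stopifnot(all(c("time_months", "event") %in% names(data)),
            all(covariates %in% names(data)), length(covariates) >= 1L)
  d <- data
  over <- d$time_months > max_follow_up
  d$event[over] <- 0L
  d$time_months[over] <- max_follow_up
  for (cv in covariates) {
    u <- unique(d[[cv]])
    if (length(u[!is.na(u)]) < 2L)
      stop("covariate has no variation: ", cv)
  }
  if (sum(d$event) < length(covariates) + 1L)
    stop(sprintf("too few events (%d) for %d covariate(s)",
                 sum(d$event), length(covariates)))
  f <- as.formula(paste("survival::Surv(time_months, event) ~",
                        paste(sprintf("`%s`", covariates), collapse = " + ")))
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = ties),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("ran out of iterations", msg, ignore.case = TRUE))
        stop("Cox fit did not converge: ", msg, call. = FALSE)
      flags <<- c(flags, msg)
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    flags <- c(flags, "singular")   # collinear column dropped as NA
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- sm$conf.int
  term <- rownames(co)
  # map each coefficient back to the covariate it came from
  assign_idx <- fit$assign
  var_of_term <- rep(NA_character_, nrow(co))
  term_labels <- attr(fit$terms, "term.labels")
  for (j in seq_along(assign_idx))
    var_of_term[assign_idx[[j]]] <- gsub("`", "", term_labels[j])
  flag <- if (length(flags))
    paste(unique(ifelse(grepl("infinite|converge", flags), "separation",
                        ifelse(grepl("singular", flags), "singular",
                               "warning"))), collapse = ";")
  else ""
  out <- data.frame(variable = var_of_term, term = term,
                    hr = unname(co[, "exp(coef)"]),
                    ci_low = unname(ci[, 3L]), ci_high = unname(ci[, 4L]),
                    p = unname(co[, "Pr(>|z|)"]),
                    n = sm$n, n_events = sm$nevent,
                    flag = flag, model = model_tag)
  rownames(out) <- NULL
  out
}

#' Univariate survival screen feeding one multivariate Cox model
#'
#' Each gene's expression is dichotomized high/low and fitted in a
#' univariate Cox model, as is each clinical covariate. Variables with
#' univariate Wald p below `alpha_in` enter a single multivariate model.
#' Singular or separated multivariate fits are returned flagged, not
#' raised.
#'
#' @param clinical data.frame with `id`, `time_months`, `event` and any
#'   clinical covariates.
#' @param expr an [expression_matrix()] (tumor columns matched to
#'   `clinical$id`), or NULL to screen clinical covariates only.
#' @param genes gene symbols to screen; default all rows of `expr`.
#' @param covariates clinical covariate column names.
#' @param alpha_in univariate inclusion threshold, default 0.05.
#' @param quantile dichotomization quantile, default 0.75.
#' @param max_follow_up administrative censoring horizon, months.
#' @return list: `univariate` (one row per variable), `multivariate`
#'   (NULL when nothing passes, with a message), `selected` variable
#'   names.
#' @export
univariate_screen <- function(clinical, expr = NULL, genes = NULL,
                              covariates = character(), alpha_in = 0.05,
                              quantile = 0.75, max_follow_up = 60) {
  stopifnot(all(c("id", "time_months", "event") %in% names(clinical)),
            !anyDuplicated(clinical$id))
  d0 <- clinical
  gene_cols <- character()
  if (!is.null(expr)) {
    stopifnot(inherits(expr, "expression_matrix"))
    if (is.null(genes)) genes <- rownames(expr$values)
    genes <- intersect(genes, rownames(expr$values))
    em <- expr$values[, match(clinical$id, colnames(expr$values)),
                      drop = FALSE]
    if (anyNA(em)) stop("clinical ids missing from the expression matrix")
    for (g in genes) {
      grp <- tryCatch(dichotomize_expression(em[g, ], quantile = quantile),
                      error = function(e) NULL)
      if (is.null(grp)) next
      d0[[g]] <- grp
      gene_cols <- c(gene_cols, g)
    }
  }
  vars <- c(gene_cols, covariates)
  uni <- do.call(rbind, lapply(vars, function(v) {
    tryCatch(cox_fit(d0, v, max_follow_up = max_follow_up,
                     model_tag = "univariate"),
             error = function(e)
               data.frame(variable = v, term = v, hr = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                          n = nrow(d0), n_events = sum(d0$event),
                          flag = conditionMessage(e), model = "univariate"))
  }))
  rownames(uni) <- NULL
  sel <- unique(uni$variable[!is.na(uni$p) & uni$p < alpha_in])
  multi <- NULL
  if (!length(sel)) {
    message("no variable passed the univariate filter; ",
            "multivariate model skipped")
  } else {
    multi <- tryCatch(
      cox_fit(d0, sel, max_follow_up = max_follow_up,
              model_tag = "multivariate"),
      error = function(e) {
        message("multivariate fit failed: ", conditionMessage(e))
        NULL
      })
  }
  list(univariate = uni, multivariate = multi, selected = sel)
}
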