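# Orchestration of the full screen: simulate (or load) the cohort, score
# recurrent copy-number alterations, test copy-number/expression
# concordance, score shRNA vulnerability, run the survival screen, and
# intersect the evidence layers into one ranked candidate table.

#' Pipeline configuration
#'
#' Collects every stage parameter in one serializable object, validated
#' up front so a bad setting is rejected before any computation.
#'
#' @param sim a [sim_config()] describing the cohort to simulate.
#' @param theta_gain,theta_loss gain/loss calling thresholds (log2).
#' @param cna_B copy-number permutation count (>= 100).
#' @param q_cutoff peak FDR cutoff, default 0.25.
#' @param arm_fraction arm-level carriage threshold, default 0.5.
#' @param alpha concordance significance threshold, default 1e-6.
#' @param direction_min copy-number direction gate, default 0.1.
#' @param vuln_B vulnerability permutation count, default 1000.
#' @param vuln_q lineage-essentiality FDR cutoff, default 0.1.
#' @param target_lineage lineage contrasted against all others.
#' @param alpha_in univariate survival inclusion threshold, default 0.05.
#' @param quantile expression dichotomization quantile, default 0.75.
#' @param max_follow_up administrative censoring horizon, months.
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir output directory for [run_pipeline()].
#' @export
pipeline_config <- function(sim = sim_config(),
                            theta_gain = 0.1, theta_loss = -0.1,
                            cna_B = 100L, q_cutoff = 0.25,
                            arm_fraction = 0.5,
                            alpha = 1e-6, direction_min = 0.1,
                            vuln_B = 1000L, vuln_q = 0.1,
                            target_lineage = "esophagus",
                            alpha_in = 0.05, quantile = 0.75,
                            max_follow_up = 60,
                            seed = 1L, outdir = tempfile("dgscreen_run_")) {
  cfg <- structure(
    list(sim = sim, theta_gain = theta_gain, theta_loss = theta_loss,
         cna_B = as.integer(cna_B), q_cutoff = q_cutoff,
         arm_fraction = arm_fraction, alpha = alpha,
         direction_min = direction_min, vuln_B = as.integer(vuln_B),
         vuln_q = vuln_q, target_lineage = target_lineage,
         alpha_in = alpha_in, quantile = quantile,
         max_follow_up = max_follow_up, seed = as.integer(seed),
         outdir = outdir),
    class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg$sim, "sim_config"))
  if (cfg$cna_B < 100L)
    stop("cna_B must be at least 100 (permutation null too coarse)")
  if (cfg$vuln_B < 1L) stop("vuln_B must be positive")
  stopifnot(cfg$theta_gain > 0, cfg$theta_loss < 0,
            cfg$q_cutoff > 0, cfg$q_cutoff < 1,
            cfg$arm_fraction > 0, cfg$arm_fraction < 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$vuln_q > 0, cfg$vuln_q < 1,
            cfg$alpha_in > 0, cfg$alpha_in < 1,
            cfg$quantile > 0, cfg$quantile < 1,
            cfg$max_follow_up > 0)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] defaults; a `sim` mapping
#' overrides [sim_config()] defaults.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  args <- c(list(sim = do.call(sim_config, sim_args)), y)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

split_genes <- function(genes) {
  g <- unlist(strsplit(genes, ",", fixed = TRUE))
  g[nzchar(g)]
}

#' Intersect the evidence layers into a ranked candidate table
#'
#' Every gene appearing in any layer report gets five flags -- inside a
#' recurrence peak, concordant copy-number/expression change,
#' prognostic in the univariate screen, prognostic in the multivariate
#' model, lineage-specifically vulnerable -- and is ranked by evidence
#' count (descending), then best peak q, then vulnerability q, then
#' symbol. The full table is returned, not only the top hits.
#'
#' @param peaks data.frame from [detect_peaks()]/[candidate_targets()].
#' @param concordance data.frame from [concordance_screen()], or NULL.
#' @param surv list from [univariate_screen()], or NULL.
#' @param vuln data.frame from [lineage_specific_genes()], or NULL.
#' @param annotation optional (gene, chromosome, start, end); duplicated
#'   symbols are an error.
#' @param alpha_in prognostic-flag threshold on Cox Wald p, default 0.05.
#' @return data.frame: gene, locus, in_peak, concordant,
#'   prognostic_univariate, prognostic_multivariate, vulnerable,
#'   evidence_count, peak_min_q, vuln_q, rank.
#' @export
intersect_evidence <- function(peaks, concordance = NULL, surv = NULL,
                               vuln = NULL, annotation = NULL,
                               alpha_in = 0.05) {
  if (!is.null(annotation) && anyDuplicated(annotation$gene))
    stop("duplicated gene symbols in annotation: ",
         paste(unique(annotation$gene[duplicated(annotation$gene)]),
               collapse = ", "))
  peak_genes <- if (nrow(peaks)) split_genes(peaks$genes) else character()
  universe <- unique(c(peak_genes,
                       concordance$gene,
                       if (!is.null(surv)) surv$univariate$variable,
                       vuln$gene))
  if (!is.null(surv))
    universe <- setdiff(universe, setdiff(surv$univariate$variable,
                                          c(peak_genes, concordance$gene,
                                            vuln$gene)))
  universe <- sort(universe)
  n <- length(universe)
  peak_min_q <- rep(Inf, n)
  in_peak <- logical(n)
  for (i in seq_len(NROW(peaks))) {
    gl <- split_genes(peaks$genes[i])
    m <- match(gl, universe)
    in_peak[m] <- TRUE
    peak_min_q[m] <- pmin(peak_min_q[m], peaks$min_q[i])
  }
  conc <- universe %in% concordance$gene[concordance$concordant]
  prog_uni <- logical(n); prog_multi <- logical(n)
  if (!is.null(surv)) {
    u <- surv$univariate
    prog_uni <- universe %in% u$variable[!is.na(u$p) & u$p < alpha_in]
    if (!is.null(surv$multivariate)) {
      m <- surv$multivariate
      prog_multi <- universe %in% m$variable[!is.na(m$p) & m$p < alpha_in]
    }
  }
  vulnerable <- logical(n); vuln_q <- rep(Inf, n)
  if (!is.null(vuln)) {
    m <- match(vuln$gene, universe)
    ok <- !is.na(m)
    vulnerable[m[ok]] <- vuln$significant[ok]
    vuln_q[m[ok]] <- vuln$q[ok]
  }
  locus <- rep(NA_character_, n)
  if (!is.null(annotation)) {
    m <- match(universe, annotation$gene)
    ok <- !is.na(m)
    locus[ok] <- sprintf("%s:%d-%d", annotation$chromosome[m[ok]],
                         annotation$start[m[ok]], annotation$end[m[ok]])
  }
  out <- data.frame(gene = universe, locus = locus, in_peak = in_peak,
                    concordant = conc, prognostic_univariate = prog_uni,
                    prognostic_multivariate = prog_multi,
                    vulnerable = vulnerable,
                    peak_min_q = peak_min_q, vuln_q = vuln_q)
  out$evidence_count <- rowSums(out[c("in_peak", "concordant",
                                      "prognostic_univariate",
                                      "prognostic_multivariate",
                                      "vulnerable")])
  ord <- order(-out$evidence_count, out$peak_min_q, out$vuln_q, out$gene)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the whole screen end to end
#'
#' Stages, in order: simulate cohort and screen; G-score significance
#' track and peaks; arm-level summary; concordance screen and per-peak
#' candidate targets; vulnerability table and lineage-essentiality
#' screen; survival screen over the genes in peaks; evidence
#' intersection. All tables are written under `config$outdir` together
#' with a `run_log` echoing every parameter and per-stage wall time.
#' Identical configurations reproduce identical tables (the run_log's
#' timing lines are the only nondeterministic output).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every intermediate object and
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("dgscreen pipeline run",
                 paste0("seed: ", cfg$seed),
                 "parameters:",
                 paste0("  ", setdiff(names(cfg), c("sim", "outdir")), ": ",
                        vapply(cfg[setdiff(names(cfg), c("sim", "outdir"))],
                               function(x) paste(format(x), collapse = ","),
                               character(1))))
  timing <- character()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(code), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timing <<- c(timing,
                 sprintf("# timing %s: %.2fs", name,
                         proc.time()[["elapsed"]] - t0))
    res
  }

  cohort <- stage("simulate", simulate_cohort(cfg$sim))
  scr <- stage("simulate_screen", simulate_screen(cfg$sim))
  thr <- aberration_thresholds(cfg$theta_gain, cfg$theta_loss)

  track <- stage("cna_significance",
                 significance_track(cohort$tumor_cn, thr, B = cfg$cna_B,
                                    seed = cfg$seed + 1L))
  ab <- call_aberrations(cohort$tumor_cn, thr)
  peaks <- stage("peaks",
                 detect_peaks(track, ab$frequency, cohort$annotation,
                              q_cutoff = cfg$q_cutoff))
  arms <- stage("arm_events",
                arm_level_summary(ab$calls, cohort$tumor_cn$markers,
                                  cfg$sim$centromere_index,
                                  arm_fraction = cfg$arm_fraction))

  conc <- stage("concordance",
                concordance_screen(cohort$tumor_cn, cohort$expression,
                                   cohort$annotation, alpha = cfg$alpha,
                                   direction_min = cfg$direction_min))
  cand <- stage("candidate_targets", candidate_targets(peaks, conc))

  vt <- stage("vulnerability",
              vulnerability_table(scr$screen, B = cfg$vuln_B,
                                  seed = cfg$seed + 2L))
  vuln <- stage("lineage_essentiality",
                lineage_specific_genes(vt, scr$screen$lineage,
                                       cfg$target_lineage,
                                       q_cutoff = cfg$vuln_q,
                                       annotation = cohort$annotation))

  peak_gene_set <- unique(split_genes(peaks$genes))
  surv <- stage("survival",
                univariate_screen(cohort$clinical, cohort$expression,
                                  genes = peak_gene_set,
                                  covariates = "node_positive",
                                  alpha_in = cfg$alpha_in,
                                  quantile = cfg$quantile,
                                  max_follow_up = cfg$max_follow_up))

  candidates <- stage("intersect",
                      intersect_evidence(peaks, conc, surv, vuln,
                                         annotation = cohort$annotation,
                                         alpha_in = cfg$alpha_in))

  qtrack <- as.data.frame(track)
  surv_forest <- rbind(surv$univariate,
                       if (!is.null(surv$multivariate)) surv$multivariate)
  written <- c(peaks = "peaks.tsv", qtrack = "qtrack.tsv",
               arms = "arm_events.tsv", conc = "concordance.tsv",
               cand = "candidate_targets.tsv", vuln = "vulnerability.tsv",
               surv = "survival_forest.tsv", candidates = "candidates.tsv")
  objs <- list(peaks = peaks, qtrack = qtrack, arms = arms, conc = conc,
               cand = cand, vuln = vuln, surv = surv_forest,
               candidates = candidates)
  for (nm in names(written))
    write_tsv_table(objs[[nm]], file.path(cfg$outdir, written[[nm]]))
  write_peaks_bed(peaks, file.path(cfg$outdir, "peaks.bed"))
  writeLines(c(log_lines, "stages: simulate, cna, concordance, vulnerability, survival, intersect",
               timing),
             file.path(cfg$outdir, "run_log"))

  invisible(list(cohort = cohort, screen = scr$screen, track = track,
                 peaks = peaks, arms = arms, concordance = conc,
                 candidate_targets = cand, vuln_table = vt,
                 lineage = vuln, survival = surv, candidates = candidates,
                 outdir = cfg$outdir))
}

#' Bundled published recurrent-peak table (ESCC aCGH cohort)
#'
#' A published summary of ten significantly recurrent copy-number regions
#' from an esophageal squamous cell carcinoma aCGH cohort: cytoband,
#' q-value, wide-peak boundaries, direction, cohort aberration frequency
#' and the genes each peak contains (121 in total). Only the genes the
#' publication names are real symbols; the remaining members of
#' multi-gene peaks are placeholder identifiers
#' (`ANON_<cytoband>_<k>`) standing in for the unlisted symbols, so gene
#' counts -- not identities -- are the meaningful content.
#'
#' @return data.frame compatible with [candidate_targets()]: cytoband,
#'   chromosome, start, end, direction, min_q, frequency, n_genes, genes.
#' @export
published_peak_table <- function() {
  path <- system.file("extdata", "escc_recurrent_peaks.tsv",
                      package = "dgscreen")
  d <- read_tsv_table(path)
  stopifnot(all(lengths(strsplit(d$genes, ",")) == d$n_genes))
  d$min_q <- as.numeric(d$min_q)
  d
}
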