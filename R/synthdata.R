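# Synthetic-cohort simulator with planted ground truth. Events are
# additive on the log2 scale; genes sit on a regular grid over the marker
# track so gene <-> marker mapping is exact and zero-noise runs are
# checkable in closed form.

MARKER_SPACING_BP <- 10000L

#' Simulation configuration for a planted-truth tumor cohort
#'
#' Defines the study conditions the simulator emulates: an aCGH-style
#' marker grid, a tumor cohort with planted focal and arm-level
#' copy-number events, dosage-driven expression against a few reference
#' normals, a pooled shRNA screen over ~100 cell lines with a small
#' target-lineage subset, and exponential survival with expression-linked
#' hazards. Defaults mirror a desk-scale squamous-carcinoma cohort:
#' 60 tumors / 3 normals, 5 chromosomes x 1000 markers (10 kb spacing),
#' 1000 genes spanning 5 markers each, 100 cell lines of which 9 are the
#' esophagus lineage, 5 shRNAs per gene. Three focal events (two
#' amplicons, one deletion; amplitude 1.0 log2, prevalence 0.8), two
#' arm-level events (amplitude 0.5, prevalence 0.6) and marker noise of
#' 0.3 log2 are planted; one full-evidence driver gene ("G0541") is
#' dosage-driven (beta = 1), prognostic (log-HR 1.2 for high expression)
#' and lineage-specifically essential (effect 2.0).
#'
#' @param n_chromosomes,markers_per_chromosome marker grid shape.
#' @param centromere_index within-chromosome marker index ending the p arm.
#' @param n_tumors,n_normals cohort sizes (normals carry no events).
#' @param focal_events list of lists with fields `chrom`, `start_marker`,
#'   `end_marker` (within-chromosome indices), `direction` ("amp"/"del"),
#'   `amplitude_mean`, `amplitude_sd` (log2 units), `prevalence` in \[0,1\].
#' @param arm_events list of lists with `chrom`, `arm` ("p"/"q"),
#'   `direction`, `prevalence`, `amplitude_mean`.
#' @param marker_noise_sd per-marker Gaussian noise, log2 units.
#' @param n_genes,markers_per_gene gene grid: gene i spans markers
#'   `(i-1)*markers_per_gene + 1 .. i*markers_per_gene` in genome order.
#' @param dosage_genes data.frame (gene, beta): expression log2 change per
#'   copy-number log2 unit.
#' @param expression_baseline_mean,expression_baseline_sd per-gene baseline
#'   log2 intensity distribution.
#' @param expression_noise_sd residual expression noise, log2 units.
#' @param screen list: `n_cell_lines`, `n_lineage` (target-lineage lines),
#'   `shrnas_per_gene`, `essential_genes` data.frame (gene,
#'   lineage_specific, effect_size), `screen_noise_sd`.
#' @param survival list: `baseline_hazard` (per month), `prognostic_genes`
#'   data.frame (gene, log_hr) applied to the high-expression group,
#'   `high_quantile` dichotomization quantile, `censoring_window` months of
#'   uniform censoring, `admin_censor_months`.
#' @param seed integer; fixed seed implies byte-identical outputs.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_chromosomes = 5L,
                       markers_per_chromosome = 1000L,
                       centromere_index = 500L,
                       n_tumors = 60L,
                       n_normals = 3L,
                       focal_events = default_focal_events(),
                       arm_events = default_arm_events(),
                       marker_noise_sd = 0.3,
                       n_genes = 1000L,
                       markers_per_gene = 5L,
                       dosage_genes = default_dosage_genes(),
                       expression_baseline_mean = 8,
                       expression_baseline_sd = 1,
                       expression_noise_sd = 0.5,
                       screen = default_screen_config(),
                       survival = default_survival_config(),
                       seed = 1L) {
  cfg <- structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         markers_per_chromosome = as.integer(markers_per_chromosome),
         centromere_index = as.integer(centromere_index),
         n_tumors = as.integer(n_tumors),
         n_normals = as.integer(n_normals),
         focal_events = focal_events,
         arm_events = arm_events,
         marker_noise_sd = marker_noise_sd,
         n_genes = as.integer(n_genes),
         markers_per_gene = as.integer(markers_per_gene),
         dosage_genes = dosage_genes,
         expression_baseline_mean = expression_baseline_mean,
         expression_baseline_sd = expression_baseline_sd,
         expression_noise_sd = expression_noise_sd,
         screen = screen,
         survival = survival,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

default_focal_events <- function() {
  list(
    list(chrom = 1L, start_marker = 101L, end_marker = 120L,
         direction = "amp", amplitude_mean = 1.0, amplitude_sd = 0.1,
         prevalence = 0.8),
    list(chrom = 2L, start_marker = 301L, end_marker = 320L,
         direction = "del", amplitude_mean = 1.0, amplitude_sd = 0.1,
         prevalence = 0.8),
    list(chrom = 3L, start_marker = 701L, end_marker = 715L,
         direction = "amp", amplitude_mean = 1.0, amplitude_sd = 0.1,
         prevalence = 0.8))
}

default_arm_events <- function() {
  list(
    list(chrom = 4L, arm = "q", direction = "amp", prevalence = 0.6,
         amplitude_mean = 0.5),
    list(chrom = 5L, arm = "p", direction = "del", prevalence = 0.6,
         amplitude_mean = 0.5))
}

# two dosage genes inside each planted focal region; G0541 is the driver
default_dosage_genes <- function() {
  data.frame(gene = c("G0021", "G0022", "G0261", "G0262", "G0541", "G0542"),
             beta = 1.0)
}

default_screen_config <- function() {
  list(n_cell_lines = 100L, n_lineage = 9L, shrnas_per_gene = 5L,
       essential_genes = data.frame(
         gene = c("G0541", "G0100", "G0300", "G0700", "G0900"),
         lineage_specific = TRUE,
         effect_size = 2.0),
       screen_noise_sd = 1.0)
}

default_survival_config <- function() {
  list(baseline_hazard = 0.04,
       prognostic_genes = data.frame(gene = "G0541", log_hr = 1.2),
       high_quantile = 0.75,
       censoring_window = 120,
       admin_censor_months = 60)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_chromosomes >= 1L, markers_per_chromosome >= 1L,
              n_tumors >= 1L, n_normals >= 1L, n_genes >= 1L,
              markers_per_gene >= 1L, marker_noise_sd >= 0,
              expression_noise_sd >= 0,
              centromere_index >= 1L,
              centromere_index < markers_per_chromosome)
    if (n_genes * markers_per_gene > n_chromosomes * markers_per_chromosome)
      stop("gene grid does not fit on the marker grid")
    if (markers_per_chromosome %% markers_per_gene != 0L)
      stop("markers_per_chromosome must be a multiple of markers_per_gene ",
           "so genes never straddle a chromosome boundary")
  })
  for (ev in cfg$focal_events) {
    stopifnot(ev$chrom >= 1L, ev$chrom <= cfg$n_chromosomes,
              ev$start_marker >= 1L, ev$start_marker <= ev$end_marker,
              ev$end_marker <= cfg$markers_per_chromosome,
              ev$direction %in% c("amp", "del"),
              ev$prevalence >= 0, ev$prevalence <= 1,
              ev$amplitude_mean >= 0, ev$amplitude_sd >= 0)
  }
  # reject opposite-direction focal events sharing markers: the additive
  # model would plant a contradiction the ground truth cannot express
  if (length(cfg$focal_events) > 1L) {
    for (i in seq_along(cfg$focal_events)[-1L]) {
      for (j in seq_len(i - 1L)) {
        a <- cfg$focal_events[[i]]; b <- cfg$focal_events[[j]]
        if (a$chrom == b$chrom && a$direction != b$direction &&
            a$start_marker <= b$end_marker && b$start_marker <= a$end_marker)
          stop(sprintf(
            "focal events %d and %d overlap on chromosome %d with opposite directions",
            j, i, a$chrom))
      }
    }
  }
  for (ev in cfg$arm_events) {
    stopifnot(ev$chrom >= 1L, ev$chrom <= cfg$n_chromosomes,
              ev$arm %in% c("p", "q"), ev$direction %in% c("amp", "del"),
              ev$prevalence >= 0, ev$prevalence <= 1, ev$amplitude_mean >= 0)
  }
  sc <- cfg$screen
  stopifnot(sc$n_cell_lines >= 1L, sc$shrnas_per_gene >= 1L,
            sc$screen_noise_sd >= 0)
  if (sc$n_lineage > sc$n_cell_lines)
    stop("n_lineage cannot exceed n_cell_lines")
  sv <- cfg$survival
  stopifnot(sv$baseline_hazard > 0, sv$censoring_window > 0,
            sv$admin_censor_months > 0,
            sv$high_quantile > 0, sv$high_quantile < 1)
  invisible(cfg)
}

marker_grid <- function(cfg) {
  data.frame(
    chrom = rep(seq_len(cfg$n_chromosomes), each = cfg$markers_per_chromosome),
    index = rep(seq_len(cfg$markers_per_chromosome), cfg$n_chromosomes),
    pos = rep(seq_len(cfg$markers_per_chromosome), cfg$n_chromosomes) *
      MARKER_SPACING_BP)
}

gene_annotation_from_config <- function(cfg) {
  grid <- marker_grid(cfg)
  mpg <- cfg$markers_per_gene
  first <- (seq_len(cfg$n_genes) - 1L) * mpg + 1L
  last <- first + mpg - 1L
  data.frame(gene = sprintf("G%04d", seq_len(cfg$n_genes)),
             chromosome = grid$chrom[first],
             start = grid$pos[first],
             end = grid$pos[last])
}

arm_marker_rows <- function(grid, cfg, chrom, arm) {
  which(grid$chrom == chrom &
          (if (arm == "p") grid$index <= cfg$centromere_index
           else grid$index > cfg$centromere_index))
}

#' Simulate a tumor cohort with planted copy-number, expression and
#' survival structure
#'
#' Tumor copy number at a marker is the sum of the amplitudes of the
#' planted events carried by that sample plus Gaussian marker noise;
#' carriage of each event is an independent Bernoulli draw at the event's
#' prevalence. Normals carry no events. Dosage genes express
#' `baseline + beta * CN + noise`; all other genes express baseline plus
#' noise. Survival times are exponential with hazard
#' `baseline_hazard * exp(sum of log-HRs over high-expression planted
#' prognostic genes)` (the high/low split uses [dichotomize_expression()],
#' the same operation the survival screen applies), censored uniformly
#' over the censoring window and administratively at
#' `admin_censor_months`.
#'
#' @param config a [sim_config()].
#' @return list with `tumor_cn` and `normal_cn` ([marker_matrix()]),
#'   `segments` (SEG-shaped data.frame from [markers_to_segments()]),
#'   `expression` ([expression_matrix()] whose reference columns are the
#'   normals), `annotation`, `clinical`, and `truth` (the planted regions,
#'   dosage/essential/prognostic genes and per-event carrier ids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    grid <- marker_grid(cfg)
    M <- nrow(grid)
    tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumors))
    normal_ids <- sprintf("N%02d", seq_len(cfg$n_normals))

    tum <- matrix(rnorm(M * cfg$n_tumors, 0, cfg$marker_noise_sd),
                  M, cfg$n_tumors, dimnames = list(NULL, tumor_ids))
    focal_truth <- list()
    for (k in seq_along(cfg$focal_events)) {
      ev <- cfg$focal_events[[k]]
      rows <- which(grid$chrom == ev$chrom & grid$index >= ev$start_marker &
                      grid$index <= ev$end_marker)
      carriers <- which(runif(cfg$n_tumors) < ev$prevalence)
      sgn <- if (ev$direction == "amp") 1 else -1
      if (length(carriers)) {
        amps <- sgn * rnorm(length(carriers), ev$amplitude_mean, ev$amplitude_sd)
        tum[rows, carriers] <- tum[rows, carriers] +
          rep(amps, each = length(rows))
      }
      focal_truth[[k]] <- list(
        chrom = ev$chrom, start = grid$pos[rows[1L]],
        end = grid$pos[rows[length(rows)]], direction = ev$direction,
        carriers = tumor_ids[carriers])
    }
    arm_truth <- list()
    for (k in seq_along(cfg$arm_events)) {
      ev <- cfg$arm_events[[k]]
      rows <- arm_marker_rows(grid, cfg, ev$chrom, ev$arm)
      carriers <- which(runif(cfg$n_tumors) < ev$prevalence)
      sgn <- if (ev$direction == "amp") 1 else -1
      if (length(carriers))
        tum[rows, carriers] <- tum[rows, carriers] + sgn * ev$amplitude_mean
      arm_truth[[k]] <- list(chrom = ev$chrom, arm = ev$arm,
                             direction = ev$direction,
                             carriers = tumor_ids[carriers])
    }
    nor <- matrix(rnorm(M * cfg$n_normals, 0, cfg$marker_noise_sd),
                  M, cfg$n_normals, dimnames = list(NULL, normal_ids))

    tumor_mm <- marker_matrix(grid[c("chrom", "pos")], tum)
    normal_mm <- marker_matrix(grid[c("chrom", "pos")], nor)
    annotation <- gene_annotation_from_config(cfg)

    # gene-level CN = mean of the gene's markers (genes tile the leading
    # n_genes * markers_per_gene markers of the genome)
    mpg <- cfg$markers_per_gene
    lead <- seq_len(cfg$n_genes * mpg)
    gene_cn <- rowsum(tum[lead, , drop = FALSE],
                      group = rep(seq_len(cfg$n_genes), each = mpg)) / mpg
    rownames(gene_cn) <- annotation$gene

    baseline <- rnorm(cfg$n_genes, cfg$expression_baseline_mean,
                      cfg$expression_baseline_sd)
    beta <- setNames(numeric(cfg$n_genes), annotation$gene)
    beta[cfg$dosage_genes$gene] <- cfg$dosage_genes$beta
    E_tum <- baseline + beta * gene_cn +
      matrix(rnorm(cfg$n_genes * cfg$n_tumors, 0, cfg$expression_noise_sd),
             cfg$n_genes, cfg$n_tumors)
    E_nor <- baseline +
      matrix(rnorm(cfg$n_genes * cfg$n_normals, 0, cfg$expression_noise_sd),
             cfg$n_genes, cfg$n_normals)
    expr_values <- cbind(E_tum, E_nor)
    dimnames(expr_values) <- list(annotation$gene, c(tumor_ids, normal_ids))
    expr <- expression_matrix(expr_values, ref_ids = normal_ids)

    sv <- cfg$survival
    log_hazard <- rep(0, cfg$n_tumors)
    for (i in seq_len(nrow(sv$prognostic_genes))) {
      g <- sv$prognostic_genes$gene[i]
      ev <- E_tum[match(g, annotation$gene), ]
      # constant expression (degenerate zero-noise configs) defines no
      # high group; the gene then contributes no hazard
      if (max(ev) > min(ev)) {
        grp <- dichotomize_expression(ev, quantile = sv$high_quantile)
        log_hazard <- log_hazard +
          sv$prognostic_genes$log_hr[i] * (grp == "high")
      }
    }
    t_event <- rexp(cfg$n_tumors, rate = sv$baseline_hazard * exp(log_hazard))
    t_cens <- runif(cfg$n_tumors, 0, sv$censoring_window)
    t_lim <- pmin(t_cens, sv$admin_censor_months)
    clinical <- data.frame(
      id = tumor_ids,
      time_months = pmin(t_event, t_lim),
      event = as.integer(t_event <= t_lim),
      node_positive = rbinom(cfg$n_tumors, 1L, 0.5))

    truth <- list(
      planted_driver_regions = do.call(rbind, lapply(focal_truth, function(x)
        data.frame(chrom = x$chrom, start = x$start, end = x$end,
                   direction = x$direction,
                   n_carriers = length(x$carriers)))),
      focal_carriers = focal_truth,
      arm_carriers = arm_truth,
      planted_dosage_genes = cfg$dosage_genes,
      planted_lineage_essential_genes = cfg$screen$essential_genes,
      planted_prognostic_genes = sv$prognostic_genes)

    list(tumor_cn = tumor_mm, normal_cn = normal_mm,
         segments = markers_to_segments(tumor_mm),
         expression = expr, annotation = annotation,
         clinical = clinical, truth = truth)
  })
}

#' Simulate a pooled shRNA depletion screen
#'
#' Every gene gets `shrnas_per_gene` hairpins; depletion scores are
#' Gaussian noise minus `effect_size` wherever the gene is essential
#' (lineage-specific genes only in target-lineage lines, pan-essential
#' genes everywhere). Lower score = stronger growth inhibition. The screen
#' RNG stream is decoupled from the cohort stream by a fixed seed offset
#' so cohort and screen are independently reproducible.
#'
#' @param config a [sim_config()].
#' @return list with `screen` (a [screen_matrix()]: scores, shRNA-to-gene
#'   map, lineage labels; the first `n_lineage` lines are the
#'   `"esophagus"` lineage) and `truth` (the planted essential genes).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sc <- cfg$screen
  with_seed(cfg$seed + 500009L, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    map <- data.frame(
      shrna = sprintf("%s_sh%d", rep(genes, each = sc$shrnas_per_gene),
                      rep(seq_len(sc$shrnas_per_gene), cfg$n_genes)),
      gene = rep(genes, each = sc$shrnas_per_gene))
    line_ids <- sprintf("CL%03d", seq_len(sc$n_cell_lines))
    lineage <- setNames(
      c(rep("esophagus", sc$n_lineage),
        rep(c("lung", "breast", "colon", "ovary", "skin"),
            length.out = sc$n_cell_lines - sc$n_lineage)),
      line_ids)
    S <- nrow(map)
    scores <- matrix(rnorm(S * sc$n_cell_lines, 0, sc$screen_noise_sd),
                     S, sc$n_cell_lines,
                     dimnames = list(map$shrna, line_ids))
    ess <- sc$essential_genes
    for (i in seq_len(NROW(ess))) {
      rows <- which(map$gene == ess$gene[i])
      cols <- if (isTRUE(ess$lineage_specific[i]))
        which(lineage == "esophagus") else seq_len(sc$n_cell_lines)
      scores[rows, cols] <- scores[rows, cols] - ess$effect_size[i]
    }
    list(screen = screen_matrix(scores, map, lineage),
         truth = list(planted_lineage_essential_genes = ess))
  })
}

#' Collapse a marker matrix to SEG-shaped segments
#'
#' Run-length encodes each sample's marker values within each chromosome;
#' at zero noise this recovers the planted piecewise-constant profile, and
#' re-expanding with [segments_to_markers()] reproduces the matrix
#' exactly.
#'
#' @param mm a [marker_matrix()].
#' @return data.frame with columns Sample, Chromosome, Start, End,
#'   Num_Probes, Segment_Mean (1-based inclusive bp).
#' @export
markers_to_segments <- function(mm) {
  stopifnot(inherits(mm, "marker_matrix"))
  out <- vector("list", length(mm$sample_ids))
  chroms <- unique(mm$markers$chrom)
  for (s in seq_along(mm$sample_ids)) {
    segs <- lapply(chroms, function(ch) {
      rows <- which(mm$markers$chrom == ch)
      v <- mm$values[rows, s]
      r <- rle(v)
      last <- cumsum(r$lengths)
      first <- last - r$lengths + 1L
      data.frame(Sample = mm$sample_ids[s], Chromosome = ch,
                 Start = mm$markers$pos[rows[first]],
                 End = mm$markers$pos[rows[last]],
                 Num_Probes = r$lengths, Segment_Mean = r$values)
    })
    out[[s]] <- do.call(rbind, segs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
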