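# Bivariate copy-number / expression concordance: a gene is a candidate
# target when both its copy number (across tumors, vs the diploid zero)
# and its expression (vs the reference-normal mean) shift significantly
# in the same direction -- the "equally directed abnormality" criterion.

#' Expression matrix with designated reference normals
#'
#' @param values genes x samples matrix of log2 intensities, finite, with
#'   row and column names.
#' @param ref_ids sample ids of the reference normals (>= 1), disjoint
#'   from the tumor ids.
#' @export
expression_matrix <- function(values, ref_ids) {
  stopifnot(is.matrix(values), all(is.finite(values)),
            !is.null(rownames(values)), !is.null(colnames(values)),
            length(ref_ids) >= 1L, all(ref_ids %in% colnames(values)))
  tumor_ids <- setdiff(colnames(values), ref_ids)
  stopifnot(length(tumor_ids) >= 1L)
  structure(list(values = values, ref_ids = ref_ids, tumor_ids = tumor_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d tumors + %d reference normals\n",
              nrow(x$values), length(x$tumor_ids), length(x$ref_ids)))
  invisible(x)
}

#' Per-sample gene-level copy number
#'
#' Mean of the markers overlapping the gene span; a gene with no
#' overlapping marker takes the nearest marker on its chromosome
#' (leftmost on distance ties).
#'
#' @param gene gene symbol present in `annotation`.
#' @param mm a [marker_matrix()].
#' @param annotation data.frame (gene, chromosome, start, end).
#' @return named numeric vector, one value per sample.
#' @export
gene_copy_values <- function(gene, mm, annotation) {
  stopifnot(inherits(mm, "marker_matrix"))
  a <- annotation[match(gene, annotation$gene), ]
  if (anyNA(a$gene)) stop("gene not found in annotation: ", gene)
  rows <- which(mm$markers$chrom == a$chromosome)
  if (!length(rows))
    stop(sprintf("chromosome %s of gene %s absent from the marker matrix",
                 as.character(a$chromosome), gene))
  hit <- rows[mm$markers$pos[rows] >= a$start & mm$markers$pos[rows] <= a$end]
  if (length(hit))
    return(colMeans(mm$values[hit, , drop = FALSE]))
  d <- abs(mm$markers$pos[rows] - (a$start + a$end) / 2)
  mm$values[rows[which.min(d)], ]
}

#' Tumor-versus-reference expression ratios
#'
#' Per-tumor log2 ratio: tumor value minus the mean over the reference
#' normal columns.
#'
#' @param gene gene symbol (rowname of the expression matrix).
#' @param expr an [expression_matrix()].
#' @return named numeric vector over tumors.
#' @export
expression_ratio <- function(gene, expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  i <- match(gene, rownames(expr$values))
  if (is.na(i)) stop("gene not found in expression matrix: ", gene)
  ref_mean <- mean(expr$values[i, expr$ref_ids])
  expr$values[i, expr$tumor_ids] - ref_mean
}

#' Equally-directed-abnormality test for one gene
#'
#' Two one-sample Wilcoxon signed-rank tests across tumors -- copy number
#' against the diploid zero, expression ratio against the reference zero
#' -- gated by direction agreement. The copy-number direction is the sign
#' of the median only when its magnitude reaches `direction_min` (the
#' +/-0.1 log2 gain/loss definition); the expression direction is the
#' sign of the median with no magnitude gate. The gene is concordant iff
#' both p-values fall below `alpha` and the two nonzero directions agree.
#'
#' @param cn_values per-tumor gene copy number ([gene_copy_values()]).
#' @param expr_ratios per-tumor expression ratios ([expression_ratio()]).
#' @param alpha significance threshold for both tests, default 1e-6.
#' @param direction_min copy-number direction gate, default 0.1 log2.
#' @param warn_small warn when fewer than 21 tumors (alpha then
#'   unreachable by the exact test).
#' @return list: cn_p, expr_p, cn_direction, expr_direction, concordant,
#'   alpha.
#' @export
concordance_test <- function(cn_values, expr_ratios, alpha = 1e-6,
                             direction_min = 0.1, warn_small = TRUE) {
  stopifnot(length(cn_values) == length(expr_ratios))
  n <- length(cn_values)
  if (warn_small && n < 21L)
    warning(sprintf(
      "only %d tumors: the exact signed-rank floor 2^-(n-1) cannot reach alpha = %g",
      n, alpha))
  one_side <- function(v) {
    if (all(v == 0)) return(list(p = 1, med = 0))
    ht <- signed_rank_test(v, alternative = "two_sided")
    list(p = ht$p_value, med = median(v))
  }
  cn <- suppressWarnings(one_side(cn_values))
  ex <- suppressWarnings(one_side(expr_ratios))
  cn_dir <- if (abs(cn$med) >= direction_min) {
    if (cn$med > 0) "+" else "-"
  } else "0"
  ex_dir <- if (ex$med > 0) "+" else if (ex$med < 0) "-" else "0"
  list(cn_p = cn$p, expr_p = ex$p,
       cn_direction = cn_dir, expr_direction = ex_dir,
       concordant = cn$p < alpha && ex$p < alpha &&
         cn_dir != "0" && cn_dir == ex_dir,
       alpha = alpha)
}

#' Concordance screen over all annotated genes
#'
#' Runs [concordance_test()] for every gene in the annotation, mapping
#' copy number through [gene_copy_values()] and expression through
#' [expression_ratio()].
#'
#' @param mm tumor [marker_matrix()].
#' @param expr an [expression_matrix()] (reference normals designated).
#' @param annotation data.frame (gene, chromosome, start, end).
#' @param alpha,direction_min as in [concordance_test()].
#' @return data.frame, one row per gene: gene, cn_p, expr_p,
#'   cn_direction, expr_direction, concordant.
#' @export
concordance_screen <- function(mm, expr, annotation, alpha = 1e-6,
                               direction_min = 0.1) {
  n_tum <- length(expr$tumor_ids)
  if (n_tum < 21L)
    warning(sprintf(
      "only %d tumors: alpha = %g is unreachable by the exact signed-rank test",
      n_tum, alpha))
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation$gene[i]
    cn <- gene_copy_values(g, mm, annotation)[expr$tumor_ids]
    er <- expression_ratio(g, expr)
    r <- concordance_test(cn, er, alpha = alpha,
                          direction_min = direction_min, warn_small = FALSE)
    data.frame(gene = g, cn_p = r$cn_p, expr_p = r$expr_p,
               cn_direction = r$cn_direction,
               expr_direction = r$expr_direction,
               concordant = r$concordant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-peak candidate-target report
#'
#' For each recurrence peak: the genes it contains and, among them, the
#' candidate targets -- genes flagged concordant whose shared direction
#' matches the peak's (amplified gene up, deleted gene down). Rows are
#' ordered by peak q-value. With `results = NULL` the report carries the
#' peak gene inventory with empty candidate lists (useful for summarising
#' an externally published peak table).
#'
#' @param peaks data.frame from [detect_peaks()] (or a compatible
#'   published peak table with `direction`, `min_q`, `n_genes`, `genes`).
#' @param results concordance data.frame from [concordance_screen()], or
#'   NULL.
#' @return `peaks` ordered by `min_q`, with `candidate_targets`
#'   (comma-separated) and `n_candidates` appended.
#' @export
candidate_targets <- function(peaks, results = NULL) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("direction", "min_q", "n_genes", "genes") %in% names(peaks)))
  cand <- character(nrow(peaks))
  n_cand <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gl <- strsplit(peaks$genes[i], ",", fixed = TRUE)[[1L]]
    gl <- gl[nzchar(gl)]
    if (is.null(results) || !length(gl)) next
    want_dir <- if (peaks$direction[i] == "amplification") "+" else "-"
    hit <- results$gene %in% gl & results$concordant &
      results$cn_direction == want_dir
    cand[i] <- paste(results$gene[hit], collapse = ",")
    n_cand[i] <- sum(hit)
  }
  peaks$candidate_targets <- cand
  peaks$n_candidates <- n_cand
  peaks[order(peaks$min_q), , drop = FALSE]
}
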