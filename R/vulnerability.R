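# shRNA-screen vulnerability scoring: per cell line, shRNAs are ranked by
# depletion; a gene's essentiality is the KS-style top-enrichment of its
# hairpins in that ranking, converted to -log10 permutation p. Lineage-
# specific essentiality contrasts these scores between a target lineage
# and all other lines.

#' Pooled shRNA screen container
#'
#' @param scores shRNA x cell-line matrix of depletion scores (lower =
#'   stronger growth inhibition), finite, with dimnames.
#' @param map data.frame (shrna, gene); every shRNA maps to one gene.
#' @param lineage character vector of lineage labels named by cell line;
#'   at least two distinct lineages.
#' @export
screen_matrix <- function(scores, map, lineage) {
  stopifnot(is.matrix(scores), all(is.finite(scores)),
            !is.null(rownames(scores)), !is.null(colnames(scores)),
            all(c("shrna", "gene") %in% names(map)),
            !anyDuplicated(map$shrna),
            setequal(rownames(scores), map$shrna),
            all(colnames(scores) %in% names(lineage)),
            length(unique(lineage[colnames(scores)])) >= 2L)
  map <- map[match(rownames(scores), map$shrna), ]
  structure(list(scores = scores, map = map,
                 lineage = lineage[colnames(scores)]),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf(
    "<screen_matrix> %d shRNAs / %d genes x %d cell lines (%d lineages)\n",
    nrow(x$scores), length(unique(x$map$gene)), ncol(x$scores),
    length(unique(x$lineage))))
  invisible(x)
}

#' Rank shRNAs by depletion in one cell line
#'
#' Ascending by depletion score so the strongest growth inhibitor is rank
#' 1; ties keep input order (stable sort).
#'
#' @param screen a [screen_matrix()].
#' @param cell_line column name.
#' @param decreasing set TRUE for screens where higher score = stronger
#'   inhibition.
#' @return character vector of shRNA ids in rank order.
#' @export
rank_shrnas <- function(screen, cell_line, decreasing = FALSE) {
  stopifnot(inherits(screen, "screen_matrix"))
  if (!cell_line %in% colnames(screen$scores))
    stop("cell line not in screen: ", cell_line)
  v <- screen$scores[, cell_line]
  if (anyNA(v))
    stop("missing scores for shRNAs: ",
         paste(rownames(screen$scores)[is.na(v)], collapse = ", "))
  rownames(screen$scores)[order(if (decreasing) -v else v)]
}

# shared helper: max running enrichment for sorted hit ranks h (len k)
ks_stat_sorted <- function(h, k, N) {
  i <- seq_len(k)
  max(0, max(i / k - (h - i) / (N - k)))
}

#' Vulnerability score of one gene in one cell line
#'
#' D = [ks_enrichment_stat()] of the gene's shRNA ranks in the cell
#' line's depletion ordering; p = permutation p-value against D of
#' uniformly drawn same-size rank sets; the score is `-log10 p`, bounded
#' above by `log10(B + 1)` by the pseudocount.
#'
#' @param screen a [screen_matrix()].
#' @param cell_line column name.
#' @param gene gene symbol in the shRNA map.
#' @param B permutation draws, default 1000.
#' @param seed RNG seed for the null draws.
#' @param decreasing see [rank_shrnas()].
#' @return list: gene, cell_line, D, p, v.
#' @export
gene_vulnerability <- function(screen, cell_line, gene, B = 1000L,
                               seed = 1L, decreasing = FALSE) {
  stopifnot(inherits(screen, "screen_matrix"))
  if (!gene %in% screen$map$gene)
    stop("gene absent from the shRNA map: ", gene)
  ord <- rank_shrnas(screen, cell_line, decreasing = decreasing)
  N <- length(ord)
  hits <- sort(match(screen$map$shrna[screen$map$gene == gene], ord))
  D <- ks_enrichment_stat(N, hits)
  k <- length(hits)
  p <- permutation_pvalue(D, function(b) {
    vapply(seq_len(b), function(i)
      ks_stat_sorted(sort(sample.int(N, k)), k, N), numeric(1))
  }, B = B, seed = seed)
  list(gene = gene, cell_line = cell_line, D = D, p = p, v = -log10(p))
}

#' Gene x cell-line vulnerability score table
#'
#' Computes the KS enrichment statistic for every gene in every cell line
#' and converts it to `-log10` permutation p-values. The permutation null
#' of the statistic depends only on the universe size and the hit-set
#' size, so one B-draw null is computed per distinct shRNA-set size and
#' shared across genes and cell lines (identical null, drawn once;
#' deterministic given `seed`).
#'
#' @param screen a [screen_matrix()].
#' @param B permutation draws per hit-set size, default 1000.
#' @param seed RNG seed.
#' @param decreasing see [rank_shrnas()].
#' @return object of class `vuln_table`: list with `v` (gene x cell-line
#'   matrix of scores), `B`, `seed`.
#' @export
vulnerability_table <- function(screen, B = 1000L, seed = 1L,
                                decreasing = FALSE) {
  stopifnot(inherits(screen, "screen_matrix"))
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  genes <- unique(screen$map$gene)
  gidx <- split(seq_len(nrow(screen$scores)), screen$map$gene)[genes]
  ks <- lengths(gidx)
  N <- nrow(screen$scores)
  L <- ncol(screen$scores)

  null_sorted <- with_seed(seed, {
    lapply(sort(unique(ks)), function(k) {
      sort(vapply(seq_len(B), function(b)
        ks_stat_sorted(sort(sample.int(N, k)), k, N), numeric(1)))
    })
  })
  names(null_sorted) <- as.character(sort(unique(ks)))

  v <- matrix(NA_real_, length(genes), L,
              dimnames = list(genes, colnames(screen$scores)))
  sgn <- if (decreasing) -1 else 1
  for (kk in sort(unique(ks))) {
    sel <- which(ks == kk)
    idx_mat <- matrix(unlist(gidx[sel]), nrow = kk)
    ns <- null_sorted[[as.character(kk)]]
    i <- seq_len(kk)
    for (c in seq_len(L)) {
      r <- rank(sgn * screen$scores[, c], ties.method = "first")
      H <- matrix(r[idx_mat], nrow = kk)
      H <- apply(H, 2L, sort)
      if (kk == 1L) H <- matrix(H, nrow = 1L)
      run <- i / kk - (H - i) / (N - kk)
      D <- pmax(do.call(pmax, as.data.frame(t(run))), 0)
      cnt_ge <- B - findInterval(D, ns, left.open = TRUE)
      v[sel, c] <- -log10((1 + cnt_ge) / (B + 1))
    }
  }
  structure(list(v = v, B = B, seed = seed), class = "vuln_table")
}

#' @export
print.vuln_table <- function(x, ...) {
  cat(sprintf("<vuln_table> %d genes x %d cell lines (B = %d, seed = %d)\n",
              nrow(x$v), ncol(x$v), x$B, x$seed))
  invisible(x)
}

#' Lineage-specific essentiality screen
#'
#' Per gene, a Welch t-test contrasts vulnerability scores in the target
#' lineage against all other cell lines; q-values are Benjamini-Hochberg
#' over all genes. A gene is significant iff `q <= q_cutoff` and the
#' target-lineage mean score exceeds the others (essentiality must point
#' into the lineage).
#'
#' @param vtable a [vulnerability_table()] result.
#' @param lineage character vector of lineage labels named by cell line.
#' @param target_lineage label of the lineage of interest (>= 2 lines).
#' @param q_cutoff FDR cutoff, default 0.1.
#' @param annotation optional gene annotation to report a locus column.
#' @return data.frame ordered by p: gene, locus, t, p, q, mean_target,
#'   mean_others, significant.
#' @export
lineage_specific_genes <- function(vtable, lineage, target_lineage,
                                   q_cutoff = 0.1, annotation = NULL) {
  stopifnot(inherits(vtable, "vuln_table"))
  lin <- lineage[colnames(vtable$v)]
  if (!target_lineage %in% lin)
    stop("target lineage absent from the screen: ", target_lineage)
  tgt <- which(lin == target_lineage)
  if (length(tgt) < 2L)
    stop("target lineage needs at least 2 cell lines")
  oth <- which(lin != target_lineage)
  res <- t(vapply(seq_len(nrow(vtable$v)), function(i) {
    a <- vtable$v[i, tgt]; b <- vtable$v[i, oth]
    ht <- tryCatch(welch_t_test(a, b),
                   error = function(e) new_test_result(0, 1, "0", "welch_t"))
    c(ht$statistic, ht$p_value, mean(a), mean(b))
  }, numeric(4)))
  out <- data.frame(gene = rownames(vtable$v),
                    t = res[, 1L], p = res[, 2L], q = bh_adjust(res[, 2L]),
                    mean_target = res[, 3L], mean_others = res[, 4L])
  out$significant <- out$q <= q_cutoff & out$mean_target > out$mean_others
  if (!is.null(annotation)) {
    m <- match(out$gene, annotation$gene)
    out$locus <- ifelse(is.na(m), NA_character_,
                        sprintf("%s:%d-%d", annotation$chromosome[m],
                                annotation$start[m], annotation$end[m]))
  }
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
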