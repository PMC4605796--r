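# GISTIC-style recurrent copy-number analysis: per-marker G scores,
# within-sample permutation null, BH q-values, contiguous-run peaks and
# arm-level event frequencies.

#' Marker-level log2-ratio matrix
#'
#' The cohort copy-number container: an ordered genome grid of markers and
#' a marker x sample matrix of log2 ratios versus a diploid reference.
#'
#' @param markers data.frame with columns `chrom` and `pos` (1-based bp),
#'   positions strictly increasing within each chromosome.
#' @param values numeric matrix, `nrow(markers)` x samples, finite.
#' @param sample_ids sample names; defaults to `colnames(values)`.
#' @export
marker_matrix <- function(markers, values, sample_ids = colnames(values)) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("chrom", "pos") %in% names(markers)),
            is.matrix(values), nrow(values) == nrow(markers),
            all(is.finite(values)))
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(ncol(values)))
  stopifnot(length(sample_ids) == ncol(values), !anyDuplicated(sample_ids))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  colnames(values) <- sample_ids
  structure(list(markers = markers[c("chrom", "pos")], values = values,
                 sample_ids = sample_ids),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d markers on %d chromosomes x %d samples\n",
              nrow(x$markers), length(unique(x$markers$chrom)),
              length(x$sample_ids)))
  invisible(x)
}

#' Gain/loss calling thresholds
#'
#' Log2-ratio cutoffs defining copy-number gain and loss; the defaults
#' (+0.1 / -0.1, boundary inclusive) follow the common aCGH convention
#' for calling any aberration.
#'
#' @param theta_gain positive log2 threshold for gains.
#' @param theta_loss negative log2 threshold for losses.
#' @export
aberration_thresholds <- function(theta_gain = 0.1, theta_loss = -0.1) {
  stopifnot(theta_gain > 0, theta_loss < 0)
  structure(list(theta_gain = theta_gain, theta_loss = theta_loss),
            class = "aberration_thresholds")
}

#' Expand segmented profiles onto a marker grid
#'
#' Each marker takes the mean of the unique segment covering it in each
#' sample; markers covered by no segment are imputed neutral (0) with a
#' warning so the grid stays rectangular. Overlapping segments within one
#' sample are an error (they would make the marker value ambiguous).
#'
#' @param profiles SEG-shaped data.frame (Sample, Chromosome, Start, End,
#'   Num_Probes, Segment_Mean; 1-based inclusive bp).
#' @param marker_grid data.frame with `chrom`, `pos`.
#' @param sample_ids samples to expand; defaults to those in `profiles`.
#' @return a [marker_matrix()]; attribute `n_uncovered` counts imputed
#'   marker-sample cells.
#' @export
segments_to_markers <- function(profiles, marker_grid,
                                sample_ids = unique(profiles$Sample)) {
  profiles <- as.data.frame(profiles)
  marker_grid <- as.data.frame(marker_grid)
  stopifnot(all(c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
                %in% names(profiles)),
            all(c("chrom", "pos") %in% names(marker_grid)))
  M <- nrow(marker_grid)
  vals <- matrix(0, M, length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  covered <- matrix(FALSE, M, length(sample_ids))
  for (s in seq_along(sample_ids)) {
    segs <- profiles[profiles$Sample == sample_ids[s], , drop = FALSE]
    for (i in seq_len(nrow(segs))) {
      rows <- which(marker_grid$chrom == segs$Chromosome[i] &
                      marker_grid$pos >= segs$Start[i] &
                      marker_grid$pos <= segs$End[i])
      if (any(covered[rows, s]))
        stop(sprintf(
          "overlapping segments in sample %s at chromosome %s:%d-%d",
          sample_ids[s], as.character(segs$Chromosome[i]),
          segs$Start[i], segs$End[i]))
      vals[rows, s] <- segs$Segment_Mean[i]
      covered[rows, s] <- TRUE
    }
  }
  n_unc <- sum(!covered)
  if (n_unc > 0L)
    warning(sprintf("%d marker-sample cells uncovered; imputed neutral (0)",
                    n_unc))
  mm <- marker_matrix(marker_grid[c("chrom", "pos")], vals, sample_ids)
  attr(mm, "n_uncovered") <- n_unc
  mm
}

#' Ternary aberration calls and per-marker aberration frequency
#'
#' Gain iff value >= `theta_gain`, loss iff value <= `theta_loss`
#' (boundaries inclusive). The frequency at a marker is the fraction of
#' samples gained or lost there, the convention used for reporting a
#' peak's cohort frequency.
#'
#' @param mm a [marker_matrix()].
#' @param thresholds an [aberration_thresholds()].
#' @return list: `calls` integer matrix in \{-1, 0, +1\}, `frequency`
#'   per-marker aberrant fraction.
#' @export
call_aberrations <- function(mm, thresholds = aberration_thresholds()) {
  stopifnot(inherits(mm, "marker_matrix"))
  x <- mm$values
  calls <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  calls[x >= thresholds$theta_gain] <- 1L
  calls[x <= thresholds$theta_loss] <- -1L
  list(calls = calls, frequency = rowMeans(calls != 0L))
}

#' Per-marker recurrence G score
#'
#' The G score at a marker is the cohort-mean amplitude in excess of the
#' calling threshold: `G_amp(m) = mean over samples of max(0, x - theta_gain)`
#' and `G_del(m) = mean of max(0, theta_loss - x)`. It rises with both the
#' frequency and the amplitude of the alteration, the two ingredients of
#' recurrence scoring.
#'
#' @param mm a [marker_matrix()].
#' @param thresholds an [aberration_thresholds()].
#' @param direction `"amp"` or `"del"`.
#' @return numeric vector of nonnegative per-marker scores.
#' @export
gscore_track <- function(mm, thresholds = aberration_thresholds(),
                         direction = c("amp", "del")) {
  stopifnot(inherits(mm, "marker_matrix"))
  direction <- match.arg(direction)
  x <- mm$values
  if (direction == "amp") rowMeans(pmax(x - thresholds$theta_gain, 0))
  else rowMeans(pmax(thresholds$theta_loss - x, 0))
}

#' Permutation significance of the G-score track
#'
#' The null preserves each sample's amplitude distribution but destroys
#' spatial clustering: each sample's marker values are independently
#' permuted B times, the G track recomputed, and all B x n_markers null
#' scores pooled per direction. Per-marker
#' `p = (1 + #\{null G >= observed G\}) / (1 + B * n_markers)` and q-values
#' are Benjamini-Hochberg within direction. Deterministic given `seed`.
#'
#' @param mm a [marker_matrix()].
#' @param thresholds an [aberration_thresholds()].
#' @param B number of whole-matrix permutations, at least 100.
#' @param seed integer RNG seed.
#' @return a `gscore_track` data.frame: chrom, pos, `G_amp`, `p_amp`,
#'   `q_amp`, `G_del`, `p_del`, `q_del`; attributes `B`, `seed`.
#' @export
significance_track <- function(mm, thresholds = aberration_thresholds(),
                               B = 100L, seed = 1L) {
  stopifnot(inherits(mm, "marker_matrix"))
  B <- as.integer(B)
  if (is.na(B) || B < 100L)
    stop("B must be at least 100: a coarser permutation null is unusable")
  x <- mm$values
  M <- nrow(x)
  tg <- thresholds$theta_gain; tl <- thresholds$theta_loss
  G_amp <- rowMeans(pmax(x - tg, 0))
  G_del <- rowMeans(pmax(tl - x, 0))
  null_amp <- numeric(M * B)
  null_del <- numeric(M * B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      xp <- apply(x, 2L, sample)
      idx <- ((b - 1L) * M + 1L):(b * M)
      null_amp[idx] <- rowMeans(pmax(xp - tg, 0))
      null_del[idx] <- rowMeans(pmax(tl - xp, 0))
    }
  })
  pooled_p <- function(obs, null) {
    ns <- sort(null)
    cnt_ge <- length(ns) - findInterval(obs, ns, left.open = TRUE)
    (1 + cnt_ge) / (1 + length(ns))
  }
  p_amp <- pooled_p(G_amp, null_amp)
  p_del <- pooled_p(G_del, null_del)
  track <- data.frame(chrom = mm$markers$chrom, pos = mm$markers$pos,
                      G_amp = G_amp, p_amp = p_amp, q_amp = bh_adjust(p_amp),
                      G_del = G_del, p_del = p_del, q_del = bh_adjust(p_del))
  attr(track, "B") <- B
  attr(track, "seed") <- seed
  class(track) <- c("gscore_track", "data.frame")
  track
}

#' Extract significant peaks from a q-value track
#'
#' Within each chromosome and direction, maximal runs of contiguous
#' markers with q below the cutoff become regions. Region boundaries are
#' the first and last marker positions of the run; the peak marker is the
#' G-score argmax (leftmost on ties); the reported frequency is the
#' maximum per-marker aberration frequency over the run; genes are the
#' annotation entries overlapping the region.
#'
#' @param track a [significance_track()] result.
#' @param frequency per-marker aberration frequency
#'   (from [call_aberrations()]).
#' @param annotation data.frame (gene, chromosome, start, end) or NULL.
#' @param q_cutoff FDR cutoff, default 0.25.
#' @return data.frame, one row per peak: chromosome, start, end,
#'   direction, peak_pos, max_G, min_q, frequency, n_genes, genes
#'   (comma-separated symbols).
#' @export
detect_peaks <- function(track, frequency, annotation = NULL,
                         q_cutoff = 0.25) {
  stopifnot(inherits(track, "gscore_track"),
            length(frequency) == nrow(track))
  if (is.null(annotation) || nrow(annotation) == 0L) {
    warning("no gene annotation supplied; peaks will carry empty gene lists")
    annotation <- data.frame(gene = character(), chromosome = integer(),
                             start = integer(), end = integer())
  }
  peaks <- list()
  for (dir in c("amplification", "deletion")) {
    qcol <- if (dir == "amplification") track$q_amp else track$q_del
    gcol <- if (dir == "amplification") track$G_amp else track$G_del
    for (ch in unique(track$chrom)) {
      rows <- which(track$chrom == ch)
      sig <- qcol[rows] < q_cutoff
      if (!any(sig)) next
      r <- rle(sig)
      last <- cumsum(r$lengths); first <- last - r$lengths + 1L
      for (k in which(r$values)) {
        run <- rows[first[k]:last[k]]
        pk <- run[which.max(gcol[run])]
        start <- track$pos[run[1L]]; end <- track$pos[run[length(run)]]
        in_pk <- annotation$chromosome == ch &
          annotation$start <= end & annotation$end >= start
        peaks[[length(peaks) + 1L]] <- data.frame(
          chromosome = ch, start = start, end = end, direction = dir,
          peak_pos = track$pos[pk], max_G = gcol[pk], min_q = min(qcol[run]),
          frequency = max(frequency[run]),
          n_genes = sum(in_pk),
          genes = paste(annotation$gene[in_pk], collapse = ","))
      }
    }
  }
  if (!length(peaks))
    return(data.frame(chromosome = integer(), start = integer(),
                      end = integer(), direction = character(),
                      peak_pos = integer(), max_G = numeric(),
                      min_q = numeric(), frequency = numeric(),
                      n_genes = integer(), genes = character()))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Arm-level event frequencies
#'
#' A sample carries an arm-level event iff strictly more than
#' `arm_fraction` of the arm's markers share that direction's call. The
#' table reports the cohort carrier frequency per arm and direction.
#'
#' @param calls call matrix from [call_aberrations()].
#' @param grid marker data.frame with `chrom`, `pos` (and optionally a
#'   within-chromosome `index`; marker order is used otherwise).
#' @param centromere_index within-chromosome marker index ending the p arm
#'   (scalar, or vector named by chromosome).
#' @param arm_fraction carriage threshold, default 0.5.
#' @return data.frame: chrom, arm, direction, n_carriers, frequency.
#' @export
arm_level_summary <- function(calls, grid, centromere_index,
                              arm_fraction = 0.5) {
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) == nrow(calls))
  chroms <- unique(grid$chrom)
  cent <- if (length(centromere_index) == 1L)
    setNames(rep(centromere_index, length(chroms)), chroms)
  else centromere_index
  out <- list()
  for (ch in chroms) {
    rows <- which(grid$chrom == ch)
    idx <- seq_along(rows)
    for (arm in c("p", "q")) {
      sel <- rows[if (arm == "p") idx <= cent[[as.character(ch)]]
                  else idx > cent[[as.character(ch)]]]
      if (!length(sel)) {
        warning(sprintf("arm %s%s has no markers; skipped", ch, arm))
        next
      }
      for (dir in c("amplification", "deletion")) {
        want <- if (dir == "amplification") 1L else -1L
        carrier <- colMeans(calls[sel, , drop = FALSE] == want) > arm_fraction
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, arm = arm, direction = dir,
          n_carriers = sum(carrier),
          frequency = mean(carrier))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
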