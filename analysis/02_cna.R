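#!/usr/bin/env Rscript
# Stage 2: recurrent copy-number analysis.
#
# Reads the segmented tumor profiles back from SEG, expands them onto the
# marker grid, scores per-marker recurrence (G score), attaches
# permutation p/q-values, extracts FDR < 0.25 peaks and summarises
# arm-level events. Outputs under results/cna/.

suppressPackageStartupMessages(library(dgscreen))

seed <- 20260926L %% 1000L
dir.create("results/cna", recursive = TRUE, showWarnings = FALSE)

segs <- read_seg("results/data/tumor_cn.seg")
grid <- read_tsv_table("results/data/marker_grid.tsv")
annotation <- read_tsv_table("results/data/annotation.tsv")
mm <- segments_to_markers(segs, grid)

thr <- aberration_thresholds()              # +/- 0.1 log2, inclusive
track <- significance_track(mm, thr, B = 100L, seed = seed + 1L)
ab <- call_aberrations(mm, thr)
peaks <- detect_peaks(track, ab$frequency, annotation, q_cutoff = 0.25)
arms <- arm_level_summary(ab$calls, mm$markers, centromere_index = 500L)

write_tsv_table(as.data.frame(track), "results/cna/qtrack.tsv")
write_tsv_table(peaks, "results/cna/peaks.tsv")
write_peaks_bed(peaks, "results/cna/peaks.bed")
write_tsv_table(arms, "results/cna/arm_events.tsv")

truth <- read_tsv_table("results/data/truth_regions.tsv")
hit <- vapply(seq_len(nrow(truth)), function(i) {
  dir <- if (truth$direction[i] == "amp") "amplification" else "deletion"
  any(peaks$direction == dir & peaks$chromosome == truth$chrom[i] &
        peaks$start <= truth$end[i] & peaks$end >= truth$start[i])
}, logical(1))
message(sprintf("detected %d peaks (%d amplification, %d deletion)",
                nrow(peaks), sum(peaks$direction == "amplification"),
                sum(peaks$direction == "deletion")))
message(sprintf("planted focal regions recovered: %d / %d",
                sum(hit), length(hit)))
message(sprintf("arm-level events above 40%% frequency: %s",
                paste(sprintf("%d%s-%s (%.2f)",
                              arms$chrom, arms$arm,
                              substr(arms$direction, 1, 3),
                              arms$frequency)[arms$frequency > 0.4],
                      collapse = ", ")))
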