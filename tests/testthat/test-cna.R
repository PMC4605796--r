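grid10 <- data.frame(chrom = 1L, pos = seq(100L, 1000L, by = 100L))

test_that("segment expansion fills covered markers and imputes the rest neutral", {
  seg <- data.frame(Sample = "S1", Chromosome = 1L, Start = 1L, End = 1000L,
                    Num_Probes = 10L, Segment_Mean = 0.7)
  mm <- segments_to_markers(seg, grid10)
  expect_equal(unname(mm$values[, 1]), rep(0.7, 10))
  # empty profile: all-neutral column with a warning
  seg2 <- data.frame(Sample = character(), Chromosome = integer(),
                     Start = integer(), End = integer(),
                     Num_Probes = integer(), Segment_Mean = numeric())
  expect_warning(mm2 <- segments_to_markers(seg2, grid10, sample_ids = "S9"),
                 "uncovered")
  expect_true(all(mm2$values == 0))
  # overlapping segments are ambiguous: error names the sample and locus
  seg3 <- rbind(seg, data.frame(Sample = "S1", Chromosome = 1L, Start = 500L,
                                End = 900L, Num_Probes = 5L,
                                Segment_Mean = -1))
  expect_error(segments_to_markers(seg3, grid10), "overlapping.*S1")
})

test_that("aberration calls use inclusive thresholds and count frequencies", {
  vals <- matrix(c(0.10, -0.10, 0.0, 0.09999,
                   0.2, -0.2, 0.0, 0.05), ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  mm <- marker_matrix(data.frame(chrom = 1L, pos = 1:4 * 100L), vals)
  ab <- call_aberrations(mm)
  expect_identical(ab$calls[, "A"], c(1L, -1L, 0L, 0L))
  expect_identical(ab$calls[, "B"], c(1L, -1L, 0L, 0L))
  col <- marker_matrix(data.frame(chrom = 1L, pos = 1:1 * 100L),
                       matrix(c(0.2, -0.2, 0.0, 0.05), 1,
                              dimnames = list(NULL, paste0("S", 1:4))))
  expect_equal(call_aberrations(col)$frequency, 0.5)
})

test_that("G scores equal the direct mean-excess summation", {
  mm0 <- marker_matrix(grid10, matrix(0.05, 10, 4,
                                      dimnames = list(NULL, paste0("S", 1:4))))
  expect_true(all(gscore_track(mm0, direction = "amp") == 0))
  expect_true(all(gscore_track(mm0, direction = "del") == 0))
  one <- marker_matrix(data.frame(chrom = 1L, pos = 100L),
                       matrix(c(0.6, rep(0, 9)), 1,
                              dimnames = list(NULL, paste0("S", 1:10))))
  expect_equal(gscore_track(one, direction = "amp"), 0.05)
  set.seed(21)
  x <- matrix(rnorm(50 * 20, sd = 0.5), 50, 20,
              dimnames = list(NULL, paste0("S", 1:20)))
  mm <- marker_matrix(data.frame(chrom = 1L, pos = 1:50 * 100L), x)
  thr <- aberration_thresholds()
  expect_equal(gscore_track(mm, thr, "amp"), brute_gscore(x, 0.1, "amp"))
  expect_equal(gscore_track(mm, thr, "del"), brute_gscore(x, -0.1, "del"))
  # inflating amplitudes never decreases G
  mm2 <- marker_matrix(mm$markers, 2 * x)
  expect_true(all(gscore_track(mm2, thr, "amp") >=
                    gscore_track(mm, thr, "amp")))
})

test_that("permutation significance is null on flat data and reproducible", {
  flat <- marker_matrix(grid10, matrix(0, 10, 5,
                                       dimnames = list(NULL, paste0("S", 1:5))))
  tr <- significance_track(flat, B = 100L, seed = 4L)
  expect_true(all(tr$p_amp == 1) && all(tr$q_amp == 1))
  expect_true(all(tr$p_del == 1) && all(tr$q_del == 1))
  set.seed(31)
  x <- matrix(rnorm(40 * 8, sd = 0.3), 40, 8,
              dimnames = list(NULL, paste0("S", 1:8)))
  mm <- marker_matrix(data.frame(chrom = 1L, pos = 1:40 * 100L), x)
  t1 <- significance_track(mm, B = 100L, seed = 5L)
  t2 <- significance_track(mm, B = 100L, seed = 5L)
  expect_identical(t1$p_amp, t2$p_amp)
  expect_identical(t1$p_del, t2$p_del)
  expect_error(significance_track(mm, B = 50L), "at least 100")
})

make_track <- function(q_amp, G_amp = rev(seq_along(q_amp)) / 100) {
  n <- length(q_amp)
  tr <- data.frame(chrom = 1L, pos = seq_len(n) * 1000L,
                   G_amp = G_amp, p_amp = q_amp, q_amp = q_amp,
                   G_del = 0, p_del = 1, q_del = 1)
  class(tr) <- c("gscore_track", "data.frame")
  tr
}

test_that("peaks are maximal contiguous significant runs", {
  ann <- data.frame(gene = "GX", chromosome = 1L, start = 1500L, end = 2500L)
  none <- detect_peaks(make_track(rep(0.9, 6)), rep(0.5, 6), ann)
  expect_equal(nrow(none), 0L)
  one <- detect_peaks(make_track(c(0.9, 0.1, 0.1, 0.1, 0.9, 0.9)),
                      c(0, 0.3, 0.6, 0.4, 0, 0), ann)
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 2000L)
  expect_equal(one$end, 4000L)
  expect_equal(one$frequency, 0.6)        # max over the run
  expect_equal(one$genes, "GX")
  two <- detect_peaks(make_track(c(0.1, 0.1, 0.9, 0.1, 0.1, 0.9)),
                      rep(0.5, 6), ann)
  expect_equal(nrow(two), 2L)
  # peaks are disjoint and cover exactly the significant markers
  qs <- c(0.1, 0.1, 0.9, 0.1, 0.9, 0.1)
  tr <- make_track(qs)
  pk <- detect_peaks(tr, rep(0.5, 6), ann)
  covered <- unlist(Map(function(s, e) tr$pos[tr$pos >= s & tr$pos <= e],
                        pk$start, pk$end))
  expect_setequal(covered, tr$pos[qs < 0.25])
  expect_warning(detect_peaks(make_track(c(0.1, 0.9)), c(0.5, 0.5), NULL),
                 "no gene annotation")
})

test_that("arm-level carriage needs a strict majority of arm markers", {
  grid <- data.frame(chrom = 1L, pos = 1:10 * 100L)
  calls <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  calls[1:5, 1] <- 1L          # whole p arm gained in A
  calls[6:7, 2] <- 1L          # 2 of 5 q markers in B: below threshold
  arms <- arm_level_summary(calls, grid, centromere_index = 5L)
  amp_p <- arms[arms$arm == "p" & arms$direction == "amplification", ]
  expect_equal(amp_p$n_carriers, 1L)
  amp_q <- arms[arms$arm == "q" & arms$direction == "amplification", ]
  expect_equal(amp_q$n_carriers, 0L)
  # exactly at the fraction is not an event (strict inequality)
  calls2 <- matrix(0L, 10, 1, dimnames = list(NULL, "A"))
  calls2[1:5, 1] <- -1L
  expect_warning(
    arms2 <- arm_level_summary(calls2, grid, centromere_index = 10L,
                               arm_fraction = 0.5),
    "no markers")
  expect_equal(arms2$n_carriers[arms2$direction == "deletion" &
                                  arms2$arm == "p"], 0L)
})

test_that("simulated arm events are recovered at their exact carrier frequency", {
  cfg <- small_sim_config(
    marker_noise_sd = 0,
    arm_events = list(list(chrom = 2L, arm = "q", direction = "amp",
                           prevalence = 0.7, amplitude_mean = 0.5)))
  co <- simulate_cohort(cfg)
  ab <- call_aberrations(co$tumor_cn)
  arms <- arm_level_summary(ab$calls, co$tumor_cn$markers,
                            cfg$centromere_index)
  got <- arms$frequency[arms$chrom == 2 & arms$arm == "q" &
                          arms$direction == "amplification"]
  truth_freq <- length(co$truth$arm_carriers[[1]]$carriers) / cfg$n_tumors
  expect_equal(got, truth_freq)
})
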