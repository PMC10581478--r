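test_that("hypnogram generator spans the requested window and efficiency", {
  h <- gen_hypnogram(sleep_duration_h = 8, epoch_s = 30, seed = 1)
  expect_length(h$stages, 960)  # 8 * 3600 / 30
  expect_true(all(h$stages %in% c("WAKE", "N1", "N2", "N3", "REM")))
  expect_gte(sleep_efficiency(h), 0.92 - 0.02)

  perfect <- gen_hypnogram(efficiency_target = 1, rem_fraction_trend = 0,
                           seed = 2)
  expect_false(any(perfect$stages == "WAKE"))
})

test_that("hypnogram structure: NREM-heavy early night, no WAKE -> N3", {
  for (seed in 1:5) {
    h <- gen_hypnogram(seed = seed)
    s <- h$stages
    half <- length(s) %/% 2
    nrem <- function(x) sum(x %in% c("N2", "N3"))
    expect_gt(nrem(s[1:half]), nrem(s[(half + 1):length(s)]))
    expect_false(any(s[-length(s)] == "WAKE" & s[-1] == "N3"))
  }
})

test_that("hypnogram generation is deterministic under a fixed seed", {
  expect_identical(gen_hypnogram(seed = 7), gen_hypnogram(seed = 7))
})

test_that("hypnogram generator rejects bad parameters", {
  expect_error(gen_hypnogram(sleep_duration_h = 0), "sleep_duration_h")
  expect_error(gen_hypnogram(sleep_duration_h = -2), "sleep_duration_h")
  expect_error(gen_hypnogram(efficiency_target = 0), "efficiency_target")
  expect_error(gen_hypnogram(cycle_length_min = -90), "cycle_length_min")
})

test_that("cortisol profile has 145 samples and a post-waking peak", {
  for (seed in 1:5) {
    p <- gen_cort_profile(wake_clock = 7, seed = seed)
    expect_length(p$concentrations, 145)
    expect_true(all(p$concentrations >= 0))
    peak_h <- p$sample_times_min[which.max(p$concentrations)] / 60
    expect_gte(peak_h, 7)
    expect_lte(peak_h, 8)
  }
  # pure envelope: same property without pulses or noise
  p0 <- gen_cort_profile(wake_clock = 7, pulse_amplitude_frac = 0,
                         noise_sd = 0)
  peak_h <- p0$sample_times_min[which.max(p0$concentrations)] / 60
  expect_gte(peak_h, 7)
  expect_lte(peak_h, 8)
  # nocturnal nadir: minimum of the envelope near the configured nadir
  nadir_h <- p0$sample_times_min[which.min(p0$concentrations)] / 60
  expect_lte(pmin(abs(nadir_h - 0), 24 - abs(nadir_h - 0)), 2)
})

test_that("zero-amplitude cortisol envelope gives an all-zero profile", {
  p <- gen_cort_profile(peak_amplitude = 0, seed = 3)
  expect_true(all(p$concentrations == 0))
})

test_that("ultradian pulses appear in the detrended autocorrelation", {
  p <- gen_cort_profile(pulse_period_min = 90, seed = 4)
  t <- p$sample_times_min
  sm <- stats::loess(p$concentrations ~ t, span = 0.4)
  resid <- p$concentrations - stats::predict(sm)
  ac <- stats::acf(resid, lag.max = 15, plot = FALSE)$acf[-1]
  # expect a local maximum within +-2 samples of lag 9 (90 min / 10 min)
  win <- ac[7:11]
  peak_lag <- (7:11)[which.max(win)]
  expect_gt(max(win), 0)
  expect_true(ac[peak_lag] > ac[peak_lag - 1] && ac[peak_lag] > ac[peak_lag + 1])
})

test_that("cortisol generator rejects bad parameters", {
  expect_error(gen_cort_profile(noise_sd = -0.1), "noise_sd")
  expect_error(gen_cort_profile(pulse_period_min = 10), "pulse_period")
  expect_error(gen_cort_profile(peak_amplitude = -1), "non-negative")
})

test_that("ED cohort generator hits its sleep-fraction targets", {
  # degenerate: every group-1 event inside the subject's sleep window
  coh <- gen_ed_cohort(n_group1 = 5, n_group2 = 0, f_sleep_group1 = 1,
                       seed = 5)
  for (r in coh)
    expect_true(all(in_sleep_window(r$event_times, r$sleep_onset_clock,
                                    r$sleep_offset_clock)))

  # large-sample recovery of the target fraction (both phenotypes)
  big <- gen_ed_cohort(n_group1 = 500, n_group2 = 500,
                       mean_total_events = 60, seed = 6)
  F <- sleep_fraction(big)
  expect_lt(abs(F[["1"]] - 0.8), 0.02)
  expect_lt(abs(F[["2"]] - 0.37), 0.02)
})

test_that("ED cohort generator handles empty groups and bad offsets", {
  coh <- gen_ed_cohort(n_group1 = 0, n_group2 = 5, seed = 7)
  expect_length(coh, 5)
  expect_true(all(vapply(coh, `[[`, 1L, "group_label") == 2L))
  expect_error(gen_ed_cohort(peak_offsets_h_group2 = c(25, 0, 8)),
               "peak offsets")
  expect_error(gen_ed_cohort(n_group1 = 1), "at least 2")
  expect_error(gen_ed_cohort(f_sleep_group1 = 1.2), "sleep fractions")
})

test_that("generators are bit-identical under fixed seeds", {
  expect_identical(gen_cort_profile(seed = 11), gen_cort_profile(seed = 11))
  expect_identical(gen_ed_cohort(n_group1 = 4, n_group2 = 4, seed = 12),
                   gen_ed_cohort(n_group1 = 4, n_group2 = 4, seed = 12))
})

test_that("group-2 events form the trimodal pattern around sleep", {
  coh <- gen_ed_cohort(n_group1 = 0, n_group2 = 120,
                       mean_total_events = 60, seed = 8)
  # anchor at sleep onset so the mixture centres align across subjects
  t_anchored <- unlist(lapply(coh, function(r)
    wrap24(r$event_times - r$sleep_onset_clock)))
  pk <- density_peaks(t_anchored, bandwidth_h = 1)
  expect_gte(nrow(pk), 3)
  top3 <- sort(pk$location[1:3])
  expect_lt(min(abs(top3 - 0)), 1.5)    # sleep onset
  expect_lt(min(abs(top3 - 8)), 1.5)    # sleep offset
  expect_lt(min(abs(top3 - 16)), 1.5)   # 8 h before onset
})
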