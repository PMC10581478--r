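#' @title Synthetic physiological inputs for the ED-rhythm pipeline
#' @description Generators for hypnograms, 24-h cortisol profiles and
#'   two-phenotype epileptiform-discharge (ED) cohorts with the statistical
#'   structure the downstream analysis assumes: a night-dominant phenotype
#'   with ~80% of events during sleep, a day-dominant trimodal phenotype,
#'   ~90-min NREM/REM cycling with NREM-heavy early night, and cortisol with
#'   a circadian envelope (morning peak, nocturnal nadir) plus ultradian
#'   pulses.
#' @name synthetic_data
NULL

SLEEP_STAGES <- c("WAKE", "N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is an ordered sequence of scored sleep stages (30-s epochs by
#' default) covering the sleep window `[sleep_onset_clock, sleep_offset_clock)`
#' on the 24-h clock.
#'
#' @param stages character vector over `WAKE, N1, N2, N3, REM`.
#' @param sleep_onset_clock,sleep_offset_clock clock hours in `[0, 24)`; the
#'   window may wrap midnight.
#' @param epoch_s epoch duration in seconds (default 30).
#' @param lights_off_clock clock hour of lights off (defaults to sleep onset).
#' @param subject_id identifier.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, sleep_onset_clock, sleep_offset_clock,
                      epoch_s = 30, lights_off_clock = sleep_onset_clock,
                      subject_id = "subj") {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), SLEEP_STAGES)
  if (length(bad))
    stopf("unknown sleep stage label(s): %s", paste(bad, collapse = ", "))
  dur_h <- wrap24(sleep_offset_clock - sleep_onset_clock)
  if (dur_h <= 0) stopf("sleep window has zero duration")
  n_expect <- round(dur_h * 3600 / epoch_s)
  if (length(stages) != n_expect)
    stopf("%d stages supplied but the sleep window spans %d epochs",
          length(stages), n_expect)
  structure(list(subject_id = subject_id,
                 epoch_s = epoch_s,
                 stages = stages,
                 lights_off_clock = wrap24(lights_off_clock),
                 sleep_onset_clock = wrap24(sleep_onset_clock),
                 sleep_offset_clock = wrap24(sleep_offset_clock)),
            class = "hypnogram")
}

#' Sleep efficiency of a hypnogram
#'
#' Fraction of non-WAKE epochs between sleep onset and offset.
#' @param h a `hypnogram`.
#' @return numeric in `[0, 1]`.
#' @export
sleep_efficiency <- function(h) mean(h$stages != "WAKE")

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram> %s: %d x %ds epochs, window %.2f-%.2f h, efficiency %.3f\n",
    x$subject_id, length(x$stages), x$epoch_s, x$sleep_onset_clock,
    x$sleep_offset_clock, sleep_efficiency(x)))
  invisible(x)
}

#' Generate a synthetic hypnogram
#'
#' Semi-Markov stage model: the night is laid out as alternating NREM/REM
#' cycles of approximately `cycle_length_min`; the REM share of each cycle
#' grows across the night while the N3 (slow-wave) share shrinks, so NREM is
#' predominant during the first part of the night, as in scored
#' polysomnography. Wake epochs are then inserted at random interior
#' positions to realise the target sleep efficiency; an inserted WAKE is
#' never followed directly by N3 (the successor is demoted to N2).
#'
#' @param sleep_onset_clock habitual sleep onset, clock hours (default 23).
#' @param sleep_duration_h sleep window length in hours, in (0, 16).
#' @param cycle_length_min mean NREM/REM cycle length (default 90 min).
#' @param rem_fraction_trend per-cycle increment of the REM share
#'   (default 0.06; 0 gives a constant REM share).
#' @param efficiency_target target sleep efficiency in (0, 1]; the realised
#'   efficiency is within 0.02 of this value.
#' @param epoch_s epoch duration, seconds.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param subject_id identifier.
#' @return A `hypnogram`.
#' @export
gen_hypnogram <- function(sleep_onset_clock = 23, sleep_duration_h = 8,
                          cycle_length_min = 90, rem_fraction_trend = 0.06,
                          efficiency_target = 0.92, epoch_s = 30,
                          seed = NULL, subject_id = "synthetic") {
  if (sleep_duration_h <= 0 || sleep_duration_h >= 16)
    stopf("sleep_duration_h must be in (0, 16)")
  if (cycle_length_min <= 0) stopf("cycle_length_min must be positive")
  if (epoch_s <= 0) stopf("epoch_s must be positive")
  if (efficiency_target <= 0 || efficiency_target > 1)
    stopf("efficiency_target must be in (0, 1]")

  with_seed(seed, {
    n_epochs <- round(sleep_duration_h * 3600 / epoch_s)
    ep_per_cycle <- round(cycle_length_min * 60 / epoch_s)
    stages <- character(0)
    cyc <- 0L
    while (length(stages) < n_epochs) {
      cyc <- cyc + 1L
      # jittered cycle length (+-8%)
      n_c <- max(4L, round(ep_per_cycle * runif(1, 0.92, 1.08)))
      rem_frac <- min(0.45, 0.10 + rem_fraction_trend * (cyc - 1L))
      n_rem <- round(n_c * rem_frac)
      n_nrem <- n_c - n_rem
      n1 <- max(1L, round(0.06 * n_nrem))
      n3 <- round(n_nrem * max(0.05, 0.45 - 0.13 * (cyc - 1L)))
      n2 <- n_nrem - n1 - n3
      if (n2 < 0) { n3 <- n3 + n2; n2 <- 0L }
      # descending then ascending through N2 around the slow-wave block
      n2a <- round(0.45 * n2); n2b <- n2 - n2a
      stages <- c(stages, rep("N1", n1), rep("N2", n2a), rep("N3", n3),
                  rep("N2", n2b), rep("REM", n_rem))
    }
    stages <- stages[seq_len(n_epochs)]

    n_wake <- round((1 - efficiency_target) * n_epochs)
    if (n_wake > 0) {
      pos <- sample(2:n_epochs, n_wake)
      stages[pos] <- "WAKE"
      # no direct WAKE -> N3 transitions
      after <- pmin(pos + 1L, n_epochs)
      fix <- after[stages[after] == "N3"]
      stages[fix] <- "N2"
    }

    hypnogram(stages,
              sleep_onset_clock = sleep_onset_clock,
              sleep_offset_clock = wrap24(sleep_onset_clock + sleep_duration_h),
              epoch_s = epoch_s, subject_id = subject_id)
  })
}

#' Construct a 24-h cortisol profile
#'
#' 145 samples at 10-min spacing spanning 24 h inclusive (minutes 0 to 1440).
#'
#' @param concentrations non-negative concentrations, length 145.
#' @param subject_id identifier.
#' @param sample_times_min sampling grid in minutes from midnight.
#' @return An object of class `cort_profile`.
#' @export
cort_profile <- function(concentrations, subject_id = "subj",
                         sample_times_min = seq(0, 1440, by = 10)) {
  if (length(sample_times_min) != 145L || length(concentrations) != 145L)
    stopf("a cortisol profile has exactly 145 samples (10-min grid over 24 h)")
  if (anyNA(concentrations)) stopf("missing concentration values")
  if (any(concentrations < 0)) stopf("negative concentration values")
  structure(list(subject_id = subject_id,
                 sample_times_min = sample_times_min,
                 concentrations = as.numeric(concentrations)),
            class = "cort_profile")
}

#' @export
print.cort_profile <- function(x, ...) {
  cat(sprintf("<cort_profile> %s: 145 samples, range %.2f-%.2f\n",
              x$subject_id, min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

# Noise-free circadian + ultradian cortisol shape on a minute grid.
cort_envelope <- function(t_min, wake_clock, peak_amplitude, nadir_clock) {
  t_h <- t_min / 60
  circ <- (1 + cos(2 * pi * (t_h - (nadir_clock + 12)) / 24)) / 2
  dist_h <- pmin(abs(t_h - (wake_clock + 0.5)) %% 24,
                 24 - abs(t_h - (wake_clock + 0.5)) %% 24)
  surge <- 1.2 * exp(-0.5 * (dist_h / 1.5)^2)
  env <- circ + surge
  if (max(env) > 0) env <- env / max(env)
  peak_amplitude * env
}

#' Generate a synthetic 24-h cortisol profile
#'
#' Circadian envelope (cosine with its nadir at `nadir_clock` plus a Gaussian
#' awakening surge, so the global maximum falls within an hour of waking)
#' with superimposed ultradian Gaussian pulses of period
#' `pulse_period_min`, log-normal multiplicative sampling noise, and clipping
#' at zero. Concentrations are in the units of the envelope amplitude
#' (nominally ug/dL plasma cortisol).
#'
#' @param wake_clock habitual wake time, clock hours (default 7).
#' @param peak_amplitude envelope maximum (default 16 ug/dL).
#' @param nadir_clock clock hour of the circadian nadir (default 0).
#' @param pulse_period_min ultradian pulse period, minutes (>= 20).
#' @param pulse_amplitude_frac pulse height as a fraction of the local
#'   envelope (default 0.35).
#' @param noise_sd standard deviation of the log-normal multiplicative noise.
#' @param seed integer seed.
#' @param subject_id identifier.
#' @return A `cort_profile`.
#' @export
gen_cort_profile <- function(wake_clock = 7, peak_amplitude = 16,
                             nadir_clock = 0, pulse_period_min = 90,
                             pulse_amplitude_frac = 0.35, noise_sd = 0.12,
                             seed = NULL, subject_id = "synthetic") {
  if (pulse_period_min < 20) stopf("pulse_period_min must be >= 20 minutes")
  if (peak_amplitude < 0 || pulse_amplitude_frac < 0)
    stopf("amplitudes must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")

  with_seed(seed, {
    t_min <- seq(0, 1440, by = 10)
    env <- cort_envelope(t_min, wake_clock, peak_amplitude, nadir_clock)
    conc <- env
    if (pulse_amplitude_frac > 0) {
      phase <- runif(1, 0, pulse_period_min)
      centers <- seq(phase, 1440, by = pulse_period_min)
      sd_min <- pulse_period_min / 6
      for (ctr in centers) {
        d <- pmin(abs(t_min - ctr), 1440 - abs(t_min - ctr))
        amp <- pulse_amplitude_frac *
          cort_envelope(ctr, wake_clock, peak_amplitude, nadir_clock)
        conc <- conc + amp * exp(-0.5 * (d / sd_min)^2)
      }
    }
    if (noise_sd > 0) conc <- conc * exp(rnorm(length(conc), 0, noise_sd))
    cort_profile(pmax(conc, 0), subject_id = subject_id)
  })
}

#' Construct an ED record
#'
#' Event times of one subject's epileptiform discharges over 24 h, with the
#' subject's habitual sleep window.
#'
#' @param event_times clock hours in `[0, 24)`.
#' @param sleep_onset_clock,sleep_offset_clock sleep window, clock hours.
#' @param subject_id identifier.
#' @param group_label optional phenotype label (1 or 2).
#' @return An object of class `ed_record`.
#' @export
ed_record <- function(event_times, sleep_onset_clock, sleep_offset_clock,
                      subject_id = "subj", group_label = NULL) {
  if (any(event_times < 0 | event_times >= 24))
    stopf("event times must lie in [0, 24)")
  structure(list(subject_id = subject_id,
                 event_times = as.numeric(event_times),
                 sleep_onset_clock = wrap24(sleep_onset_clock),
                 sleep_offset_clock = wrap24(sleep_offset_clock),
                 group_label = group_label),
            class = "ed_record")
}

#' @export
print.ed_record <- function(x, ...) {
  cat(sprintf("<ed_record> %s: %d events, sleep %.2f-%.2f h%s\n",
              x$subject_id, length(x$event_times), x$sleep_onset_clock,
              x$sleep_offset_clock,
              if (is.null(x$group_label)) "" else
                sprintf(", group %d", x$group_label)))
  invisible(x)
}

# Sample event clock times for one night-dominant subject: with probability
# f_sleep an event falls inside the sleep window (early-night-skewed beta
# profile), otherwise uniformly in the wake period.
sample_group1_times <- function(n, onset, offset, f_sleep) {
  dur <- wrap24(offset - onset)
  asleep <- runif(n) < f_sleep
  t <- numeric(n)
  ns <- sum(asleep)
  t[asleep] <- wrap24(onset + dur * rbeta(ns, 1.3, 1.9))
  t[!asleep] <- wrap24(offset + (24 - dur) * runif(n - ns))
  t
}

# Sample event clock times for one day-dominant subject from a trimodal
# wrapped-Gaussian mixture centred at onset + peak_offsets_h, split so the
# expected fraction of events inside the sleep window equals f_sleep.
sample_group2_times <- function(n, onset, offset, f_sleep, peak_offsets_h,
                                peak_sd_h = 1.1) {
  draw_mix <- function(m) {
    ctr <- wrap24(onset + sample(peak_offsets_h, m, replace = TRUE))
    wrap24(rnorm(m, ctr, peak_sd_h))
  }
  want_sleep <- runif(n) < f_sleep
  t <- numeric(n)
  for (inside in c(TRUE, FALSE)) {
    idx <- which(want_sleep == inside)
    got <- numeric(0)
    while (length(got) < length(idx)) {
      cand <- draw_mix(max(64L, 2L * (length(idx) - length(got))))
      cand <- cand[in_sleep_window(cand, onset, offset) == inside]
      got <- c(got, cand)
    }
    t[idx] <- got[seq_along(idx)]
  }
  t
}

#' Generate a synthetic two-phenotype ED cohort
#'
#' Group-1 subjects draw event times from a sleep-concentrated mixture with
#' expected sleep fraction `f_sleep_group1`; group-2 subjects from a trimodal
#' daytime mixture (wrapped-Gaussian components at `sleep_onset +
#' peak_offsets_h_group2`) with expected sleep fraction `f_sleep_group2`.
#' Per-subject totals are negative-binomial around `mean_total_events`.
#'
#' @param n_group1,n_group2 group sizes (a group may be empty; a non-empty
#'   group needs >= 2 subjects).
#' @param mean_total_events mean ED count per subject over 24 h.
#' @param f_sleep_group1,f_sleep_group2 expected fraction of events inside
#'   the sleep window, in `[0, 1]`.
#' @param peak_offsets_h_group2 peak positions in hours after sleep onset,
#'   each in `[0, 24)` (defaults: 16 = 8 h before onset, 0 = onset,
#'   8 = sleep offset).
#' @param dispersion negative-binomial size parameter for the totals.
#' @param seed integer seed.
#' @return A list of [ed_record()] objects with `group_label` set.
#' @export
gen_ed_cohort <- function(n_group1 = 66, n_group2 = 41,
                          mean_total_events = 40,
                          f_sleep_group1 = 0.8, f_sleep_group2 = 0.37,
                          peak_offsets_h_group2 = c(16, 0, 8),
                          dispersion = 1.5, seed = NULL) {
  if ((n_group1 > 0 && n_group1 < 2) || (n_group2 > 0 && n_group2 < 2))
    stopf("a non-empty group needs at least 2 subjects")
  if (f_sleep_group1 < 0 || f_sleep_group1 > 1 ||
      f_sleep_group2 < 0 || f_sleep_group2 > 1)
    stopf("sleep fractions must lie in [0, 1]")
  if (any(peak_offsets_h_group2 < 0 | peak_offsets_h_group2 >= 24))
    stopf("peak offsets must lie in [0, 24) hours after sleep onset")

  with_seed(seed, {
    make <- function(i, group) {
      onset <- wrap24(rnorm(1, 23, 0.5))
      dur <- min(9.5, max(6.5, rnorm(1, 8, 0.5)))
      offset <- wrap24(onset + dur)
      n_ev <- max(1L, rnbinom(1, mu = mean_total_events, size = dispersion))
      times <- if (group == 1L)
        sample_group1_times(n_ev, onset, offset, f_sleep_group1)
      else
        sample_group2_times(n_ev, onset, offset, f_sleep_group2,
                            peak_offsets_h_group2)
      ed_record(times, onset, offset,
                subject_id = sprintf("g%d_s%03d", group, i),
                group_label = group)
    }
    c(lapply(seq_len(n_group1), make, group = 1L),
      lapply(seq_len(n_group2), make, group = 2L))
  })
}
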