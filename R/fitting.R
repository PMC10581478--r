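#' @title Fitting driver contributions to observed ED histograms
#' @description Compare simulated cohort histograms with observed ones:
#'   residual sum of squares and R-squared over the 24 hourly bins, a grid
#'   search over the sleep/cortisol weights (p_S, p_C), a simplified
#'   random-walk Metropolis-Hastings posterior, and the null-model trend
#'   regression contracts.
#' @name fitting
NULL

#' Residual sum of squares over hourly bins
#'
#' `sum((y - yhat)^2)` over the 24 bins; both curves are normally unit-sum
#' hourly fraction curves.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rss <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stopf("observed and predicted differ in length")
  sum((observed - predicted)^2)
}

#' R-squared of a histogram prediction
#'
#' `1 - RSS / TSS` with TSS about the observed mean. Negative values
#' indicate the prediction performs worse than the flat mean curve.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return Scalar (possibly negative).
#' @export
r_squared <- function(observed, predicted) {
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stopf("observed vector is constant; R-squared undefined")
  1 - rss(observed, predicted) / tss
}

#' Simulated cohort ED histogram
#'
#' For every cohort member: build the sleep and cortisol forcing signals
#' from the member's hypnogram and cortisol profile (with the member's
#' action delay), combine them with weights `(p_S, p_C)`, simulate the
#' network over 24 h, and bin pooled events hourly. Member counts are
#' pooled and normalised to a unit-sum fraction curve.
#'
#' `sim_hour_s` compresses the timeline: each clock hour is represented by
#' `sim_hour_s` simulated seconds (3600 = real time). The network dynamics
#' are fast (seconds) relative to the forcing (hours), so event rates per
#' simulated second — and hence histogram shapes — are insensitive to the
#' compression, while cost scales linearly with it.
#'
#' @param cohort a `virtual_cohort`.
#' @param p_S,p_C combination weights in `[0, 1.5]`.
#' @param model a `hopf_network`.
#' @param seed seed governing all member simulations.
#' @param sim_hour_s simulated seconds per clock hour.
#' @param return_counts return the pooled 24 count vector instead of the
#'   fraction curve.
#' @return Unit-sum numeric vector of 24 hourly fractions (or counts), with
#'   the pooled total attached as attribute `n_events`.
#' @export
simulate_cohort_histogram <- function(cohort, p_S, p_C,
                                      model = network_model(), seed = NULL,
                                      sim_hour_s = 3600,
                                      return_counts = FALSE) {
  check_weights(p_S, p_C)
  counts <- cohort_member_counts(cohort, p_S, p_C, model, seed, sim_hour_s)
  pooled <- colSums(counts)
  total <- sum(pooled)
  if (total == 0) stopf("cohort produced no events")
  out <- if (return_counts) pooled else pooled / total
  attr(out, "n_events") <- total
  out
}

# subjects x 24 matrix of simulated hourly counts, one row per member
cohort_member_counts <- function(cohort, p_S, p_C, model, seed, sim_hour_s) {
  scale <- sim_hour_s / 3600
  offs <- if (is.null(seed)) 0L else
    with_seed(seed, sample.int(.Machine$integer.max - 1L, 1))
  rows <- lapply(seq_along(cohort$members), function(i) {
    m <- cohort$members[[i]]
    s_sig <- sleep_forcing(m$hypnogram, cohort$params$r_S)
    c_sig <- cort_forcing(m$cort, cohort$params$r_C, phi_min = m$phi_min)
    comb <- compress_forcing(combine_forcing(s_sig, c_sig, p_S, p_C), scale)
    run_seed <- as.integer((as.numeric(m$seed) + as.numeric(offs)) %%
                             (.Machine$integer.max - 2)) + 1L
    sim <- simulate_hopf(model, comb, duration_s = 24 * sim_hour_s,
                         seed = run_seed,
                         burn_in_s = min(60, 6 * sim_hour_s / 3600 * 60))
    bin_events(sim, clock_offset_h = 0, seconds_per_hour = sim_hour_s)
  })
  do.call(rbind, rows)
}

#' Grid search over driver weights
#'
#' Simulates the cohort histogram at every point of a `(p_S, p_C)` grid on
#' `[0, 1.5]^2` and scores it against the observed unit-sum hourly curve by
#' RSS (and R-squared). Member simulation seeds are shared across grid
#' points (common random numbers), so differences between grid points
#' reflect the weights rather than noise realisations. The best fit is the
#' RSS minimum, ties broken toward smaller `p_S + p_C`, then smaller `p_S`.
#'
#' @param observed unit-sum 24-bin hourly fraction curve.
#' @param cohort a `virtual_cohort`.
#' @param model a `hopf_network`.
#' @param grid_step grid spacing (must divide 1.5; default 0.1).
#' @param replicates simulated histograms averaged per grid point.
#' @param seed seed for the member simulations.
#' @param sim_hour_s simulated seconds per clock hour.
#' @return An object of class `fit_grid`: `p_S_values`, `p_C_values`,
#'   `rss` and `r2` matrices (p_S by p_C), and `best`.
#' @export
grid_search <- function(observed, cohort, model = network_model(),
                        grid_step = 0.1, replicates = 1, seed = NULL,
                        sim_hour_s = 3600) {
  k <- 1.5 / grid_step
  if (abs(k - round(k)) > 1e-9) stopf("grid_step must divide 1.5")
  if (abs(sum(observed) - 1) > 1e-6)
    stopf("observed curve must be normalised to unit sum")
  p_vals <- seq(0, 1.5, by = grid_step)
  n <- length(p_vals)
  rss_m <- r2_m <- matrix(NA_real_, n, n, dimnames = list(p_vals, p_vals))
  rep_seeds <- if (is.null(seed)) rep(list(NULL), replicates) else
    as.list(seed + 7919L * (seq_len(replicates) - 1L))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      hists <- vapply(rep_seeds, function(s)
        as.numeric(simulate_cohort_histogram(cohort, p_vals[i], p_vals[j],
                                             model, seed = s,
                                             sim_hour_s = sim_hour_s)),
        numeric(24))
      h <- rowMeans(hists)
      rss_m[i, j] <- rss(observed, h)
      r2_m[i, j] <- r_squared(observed, h)
    }
  }
  best_idx <- which(rss_m == min(rss_m), arr.ind = TRUE)
  if (nrow(best_idx) > 1) {
    tot <- p_vals[best_idx[, 1]] + p_vals[best_idx[, 2]]
    best_idx <- best_idx[order(tot, p_vals[best_idx[, 1]]), , drop = FALSE]
  }
  bi <- best_idx[1, ]
  structure(list(p_S_values = p_vals, p_C_values = p_vals,
                 rss = rss_m, r2 = r2_m,
                 best = list(p_S = p_vals[bi[1]], p_C = p_vals[bi[2]],
                             rss = rss_m[bi[1], bi[2]],
                             r2 = r2_m[bi[1], bi[2]]),
                 replicates = replicates, seed = seed),
            class = "fit_grid")
}

#' @export
print.fit_grid <- function(x, ...) {
  cat(sprintf("<fit_grid> %dx%d grid; best p_S=%.2f p_C=%.2f (RSS=%.4g, R2=%.3f)\n",
              length(x$p_S_values), length(x$p_C_values),
              x$best$p_S, x$best$p_C, x$best$rss, x$best$r2))
  invisible(x)
}

#' Simplified Metropolis-Hastings posterior for the driver weights
#'
#' Random-walk Metropolis-Hastings over `(p_S, p_C)` with a uniform prior
#' on `[0, 1.5]^2` and a Gaussian likelihood on the 24 hourly fractions
#' whose scale is estimated from replicate simulation spread at the chain's
#' starting point. All likelihood evaluations share one simulation seed
#' (common random numbers), making the target a deterministic approximate
#' likelihood surface; this is a simplified variant of simulation-based
#' posterior sampling.
#'
#' @param observed unit-sum 24-bin hourly fraction curve.
#' @param cohort a `virtual_cohort`.
#' @param model a `hopf_network`.
#' @param proposal_sd random-walk proposal standard deviation (> 0).
#' @param n_iter,burn_in chain length and discarded prefix.
#' @param init starting point.
#' @param sigma_replicates replicates used to estimate the likelihood scale.
#' @param seed integer seed.
#' @param sim_hour_s simulated seconds per clock hour.
#' @return List with `samples` (matrix, columns `p_S`, `p_C`),
#'   `posterior_mean`, `acceptance_rate`, `sigma`.
#' @export
mh_mcmc <- function(observed, cohort, model = network_model(),
                    proposal_sd = 0.15, n_iter = 300, burn_in = 50,
                    init = c(0.75, 0.75), sigma_replicates = 4,
                    seed = NULL, sim_hour_s = 3600) {
  if (proposal_sd <= 0) stopf("proposal_sd must be positive")
  if (proposal_sd < 1e-6)
    warnf("proposal_sd ~ 0: the chain will not explore (degenerate)")
  if (n_iter <= burn_in) stopf("n_iter must exceed burn_in")

  sim_seed <- if (is.null(seed)) 1L else seed
  hist_at <- function(p)
    as.numeric(simulate_cohort_histogram(cohort, p[1], p[2], model,
                                         seed = sim_seed,
                                         sim_hour_s = sim_hour_s))
  # likelihood scale from replicate spread at the starting point
  reps <- vapply(seq_len(sigma_replicates), function(r)
    as.numeric(simulate_cohort_histogram(cohort, init[1], init[2], model,
                                         seed = sim_seed + 104729L * r,
                                         sim_hour_s = sim_hour_s)),
    numeric(24))
  sigma <- sqrt(mean(apply(reps, 1, var)))
  if (!is.finite(sigma) || sigma <= 0) sigma <- 0.01

  loglik <- function(h) -sum((observed - h)^2) / (2 * sigma^2)

  with_seed(seed, {
    cur <- init
    cur_ll <- loglik(hist_at(cur))
    samples <- matrix(NA_real_, n_iter, 2,
                      dimnames = list(NULL, c("p_S", "p_C")))
    n_acc <- 0L
    for (it in seq_len(n_iter)) {
      prop <- cur + rnorm(2, 0, proposal_sd)
      if (all(prop >= 0 & prop <= 1.5)) {
        prop_ll <- loglik(hist_at(prop))
        if (log(runif(1)) < prop_ll - cur_ll) {
          cur <- prop; cur_ll <- prop_ll; n_acc <- n_acc + 1L
        }
      }
      samples[it, ] <- cur
    }
    keep <- samples[(burn_in + 1):n_iter, , drop = FALSE]
    list(samples = keep,
         posterior_mean = colMeans(keep),
         acceptance_rate = n_acc / n_iter,
         sigma = sigma)
  })
}

#' Trend regression of hourly ED counts on time and sleep
#'
#' Fits `count ~ Time + asleep` by ordinary linear regression (family
#' `"linear"`), or a mixed-effects Poisson regression with a subject-level
#' random intercept, `count ~ Time + asleep + (1 | subject)` (family
#' `"poisson_mixed"`, requires >= 2 subjects). Used for the null-model
#' check: with no external forcing the time term should be flat.
#'
#' With the default `time_coding = "categorical"` the Time term enters as
#' hour-of-day categories and its p-value is a joint test over the hour
#' effects (F-test for the linear family, likelihood-ratio test for the
#' mixed family). This is the reading under which "does time of day affect
#' the count?" is answerable at all when a sleep indicator is also in the
#' model: a *linear* hour slope is nearly collinear with nothing — it is
#' blind to any time structure that is symmetric across the night, such as
#' the night-time plateau the sleep driver induces, which the `asleep`
#' term already absorbs. The linear-slope coding remains available via
#' `time_coding = "linear"`.
#'
#' @param data `data.frame` with columns `subject`, `hour` (0-23), `count`
#'   (non-negative integers) and `asleep` (0/1).
#' @param family `"linear"` or `"poisson_mixed"`.
#' @param time_coding `"categorical"` (hour dummies, joint test) or
#'   `"linear"` (single slope).
#' @return An object of class `trend_fit`: `coefficients`, `p_values`
#'   (named `hour` and `asleep`), `family`, `formula`, and the underlying
#'   `fit`.
#' @export
trend_test <- function(data, family = c("linear", "poisson_mixed"),
                       time_coding = c("categorical", "linear")) {
  family <- match.arg(family)
  time_coding <- match.arg(time_coding)
  need <- c("subject", "hour", "count", "asleep")
  if (!all(need %in% names(data)))
    stopf("data needs columns: %s", paste(need, collapse = ", "))
  if (all(data$count == 0)) stopf("all-zero response")
  if (any(data$count < 0)) stopf("counts must be non-negative")
  data$time <- if (time_coding == "categorical") factor(data$hour) else
    data$hour

  # asleep enters first: the Time term then tests time-of-day structure
  # *beyond* the sleep step (and stays well defined when homogeneous sleep
  # windows make the indicator collinear with the hour dummies)
  if (family == "linear") {
    fit <- lm(count ~ asleep + time, data = data)
    co <- coef(fit)
    av <- stats::anova(fit)
    pv <- c(hour = av["time", "Pr(>F)"],
            asleep = av["asleep", "Pr(>F)"])
    fo <- "count ~ asleep + Time"
  } else {
    if (length(unique(data$subject)) < 2)
      stopf("poisson_mixed requires at least 2 subjects")
    fit <- suppressMessages(
      lme4::glmer(count ~ asleep + time + (1 | subject), data = data,
                  family = stats::poisson))
    red <- suppressMessages(
      lme4::glmer(count ~ asleep + (1 | subject), data = data,
                  family = stats::poisson))
    co <- lme4::fixef(fit)
    pv <- c(hour = stats::anova(fit, red)[2, "Pr(>Chisq)"],
            asleep = coef(summary(fit))["asleep", "Pr(>|z|)"])
    fo <- "count ~ asleep + Time + (1 | subject)"
  }
  structure(list(coefficients = co, p_values = pv, family = family,
                 time_coding = time_coding, formula = fo, fit = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s [%s, %s time]\n", x$formula, x$family,
              x$time_coding))
  cat(sprintf("  p(Time) = %.3g, p(asleep) = %.3g\n",
              x$p_values[["hour"]], x$p_values[["asleep"]]))
  invisible(x)
}

#' Hourly count long table for a set of simulated subjects
#'
#' Helper assembling the `trend_test` input from per-subject hourly counts
#' and sleep windows. The regression time axis is anchored at
#' `hour_origin` (noon by default) so that a habitual overnight sleep
#' window is contiguous on the axis: a linear time term is blind to a
#' trend that the axis origin cuts in half, so anchoring at midnight would
#' split the night between the two ends of the axis and cancel any
#' within-night trend.
#'
#' @param counts subjects x 24 matrix of hourly counts (columns are clock
#'   hours 0-23).
#' @param sleep_onsets,sleep_offsets per-subject sleep window, clock hours.
#' @param hour_origin clock hour mapped to 0 on the regression axis.
#' @return `data.frame` with columns `subject`, `hour` (hours since
#'   `hour_origin`), `count`, `asleep`.
#' @export
trend_data <- function(counts, sleep_onsets, sleep_offsets,
                       hour_origin = 12) {
  n <- nrow(counts)
  clock <- 0:23
  axis <- wrap24(clock - hour_origin)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = sprintf("s%03d", i), hour = axis,
               count = as.numeric(counts[i, ]),
               asleep = as.integer(in_sleep_window(clock + 0.5,
                                                   sleep_onsets[i],
                                                   sleep_offsets[i])))
  }))
}
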