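#' @title Excitability forcing signals
#' @description Convert hypnograms and cortisol profiles into the
#'   time-varying external excitability input \eqn{\lambda_{ext}(t)} of the
#'   network model, and combine the two drivers linearly.
#' @name forcing
NULL

#' Forcing parameters
#'
#' Container for the driver rescale factors and combination weights.
#' `r_S` (default 0.11) rescales the sleep-stage signal; `r_C` (default
#' 0.0033) rescales cortisol concentrations; `p_S`, `p_C` in `[0, 1.5]`
#' weight the two drivers in the combined signal; `phi_mean_min` /
#' `phi_sd_min` (13 / 5 min) parameterise the per-subject cortisol action
#' delay.
#'
#' @param r_S,r_C non-negative rescale factors.
#' @param p_S,p_C combination weights in `[0, 1.5]`.
#' @param phi_mean_min,phi_sd_min cortisol delay distribution (minutes).
#' @return An object of class `forcing_params`.
#' @export
forcing_params <- function(r_S = 0.11, r_C = 0.0033, p_S = 1, p_C = 1,
                           phi_mean_min = 13, phi_sd_min = 5) {
  if (r_S < 0 || r_C < 0) stopf("rescale factors must be non-negative")
  check_weights(p_S, p_C)
  if (phi_sd_min < 0) stopf("phi_sd_min must be non-negative")
  structure(list(r_S = r_S, r_C = r_C, p_S = p_S, p_C = p_C,
                 phi_mean_min = phi_mean_min, phi_sd_min = phi_sd_min),
            class = "forcing_params")
}

check_weights <- function(p_S, p_C) {
  if (p_S < 0 || p_S > 1.5 || p_C < 0 || p_C > 1.5)
    stopf("combination weights p_S, p_C must lie in [0, 1.5]")
  invisible(TRUE)
}

#' Construct a forcing signal
#'
#' A forcing signal is a value per point of a sorted time grid (seconds).
#' `interp` records how values between grid points are meant to be read:
#' zero-order hold for categorical sources (sleep stages), linear for
#' continuous ones (hormone concentrations).
#'
#' @param time_s sorted numeric grid, seconds.
#' @param values numeric vector (shared across nodes) or matrix with one
#'   column per node.
#' @param interp `"zoh"` or `"linear"`.
#' @return An object of class `forcing_signal`.
#' @export
forcing_signal <- function(time_s, values, interp = c("zoh", "linear")) {
  interp <- match.arg(interp)
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(values) != length(time_s))
    stopf("time grid and values differ in length")
  if (is.unsorted(time_s)) stopf("time grid must be sorted")
  if (any(!is.finite(values))) stopf("forcing values must be finite")
  structure(list(time_s = as.numeric(time_s), values = values,
                 interp = interp),
            class = "forcing_signal")
}

#' @export
print.forcing_signal <- function(x, ...) {
  cat(sprintf("<forcing_signal> %d points over [%.0f, %.0f] s, %s, range %.4g-%.4g\n",
              length(x$time_s), min(x$time_s), max(x$time_s), x$interp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Evaluate a forcing signal at arbitrary times
#'
#' @param sig a `forcing_signal`.
#' @param t_s times in seconds (clamped to the grid range).
#' @return numeric vector (shared signal) or matrix.
#' @export
eval_forcing <- function(sig, t_s) {
  one <- function(v) {
    if (sig$interp == "zoh") {
      idx <- findInterval(t_s, sig$time_s, rightmost.closed = FALSE)
      v[pmax(1L, pmin(idx, length(v)))]
    } else {
      approx(sig$time_s, v, xout = pmin(pmax(t_s, min(sig$time_s)),
                                        max(sig$time_s)))$y
    }
  }
  out <- apply(sig$values, 2, one)
  if (ncol(sig$values) == 1L) as.numeric(out) else out
}

#' Constant forcing signal
#'
#' @param value constant \eqn{\lambda_{ext}} level.
#' @param duration_s covered duration in seconds.
#' @return A `forcing_signal`.
#' @export
const_forcing <- function(value, duration_s = 86400) {
  forcing_signal(c(0, duration_s), rep(value, 2), interp = "zoh")
}

# sleep stage -> excitability multiplier (before r_S rescaling)
STAGE_EXCITABILITY <- c(WAKE = 0, N1 = 0.5, N2 = 1, N3 = 1, REM = 0)

#' Sleep-stage forcing signal
#'
#' Maps each scored stage to an excitability level — 1 during N2 and N3,
#' 0.5 during N1, 0 during REM and wakefulness — rescaled by `r_S`
#' (default 0.11). The signal is piecewise constant per epoch on a 24-h
#' clock-time grid (seconds from midnight); time outside the recorded night
#' is wakefulness (0).
#'
#' @param h a `hypnogram`.
#' @param r_S sleep rescale factor.
#' @return A `forcing_signal` on a grid of `epoch_s` spacing covering 24 h.
#' @export
sleep_forcing <- function(h, r_S = 0.11) {
  if (r_S < 0) stopf("r_S must be non-negative")
  bad <- which(!(h$stages %in% names(STAGE_EXCITABILITY)))
  if (length(bad))
    stopf("unknown stage label '%s' at epoch %d", h$stages[bad[1]], bad[1])
  grid <- seq(0, 86400, by = h$epoch_s)
  vals <- numeric(length(grid))
  ep_start_s <- (h$sleep_onset_clock * 3600 +
                   (seq_along(h$stages) - 1L) * h$epoch_s) %% 86400
  slot <- round(ep_start_s / h$epoch_s) + 1L
  vals[slot] <- r_S * STAGE_EXCITABILITY[h$stages]
  forcing_signal(grid, vals, interp = "zoh")
}

#' Cortisol forcing signal
#'
#' \eqn{\lambda_{ext,CORT}(t) = r_C \cdot c(t - \phi)} where `c` is the
#' concentration profile (linear interpolation between the 10-min samples,
#' circular wrap at the 24-h boundary) and `phi` is the subject's action
#' delay in minutes. If `phi_min` is `NULL` a single delay is drawn from
#' N(13, 5) minutes truncated at zero.
#'
#' @param profile a `cort_profile`.
#' @param r_C cortisol rescale factor (default 0.0033).
#' @param phi_min delay in minutes, or `NULL` to sample.
#' @param phi_mean_min,phi_sd_min delay distribution used when sampling.
#' @param seed integer seed for the delay draw.
#' @param grid_s output grid spacing, seconds.
#' @return A `forcing_signal` covering 24 h; the realised delay is attached
#'   as attribute `phi_min`.
#' @export
cort_forcing <- function(profile, r_C = 0.0033, phi_min = NULL,
                         phi_mean_min = 13, phi_sd_min = 5, seed = NULL,
                         grid_s = 30) {
  if (r_C < 0) stopf("r_C must be non-negative")
  if (is.null(phi_min))
    phi_min <- with_seed(seed, rtruncnorm0(phi_mean_min, phi_sd_min))
  grid <- seq(0, 86400, by = grid_s)
  src_min <- grid / 60 - phi_min
  # circular wrap, but leave the inclusive 24-h endpoint in place so the
  # delay-free signal reproduces the input samples exactly
  out <- src_min < 0 | src_min > 1440
  src_min[out] <- src_min[out] %% 1440
  vals <- r_C * approx(profile$sample_times_min, profile$concentrations,
                       xout = src_min)$y
  sig <- forcing_signal(grid, vals, interp = "linear")
  attr(sig, "phi_min") <- phi_min
  sig
}

# N(mean, sd) truncated at zero (rejection; the negative tail is ~0.5%)
rtruncnorm0 <- function(mean, sd) {
  if (sd == 0) return(max(0, mean))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= 0) return(x)
  }
}

#' Combine sleep and cortisol forcing
#'
#' Pointwise linear combination `p_S * sleep + p_C * cort` on the finer of
#' the two grids (zero-order-hold resampling for stage signals, linear for
#' continuous ones). Weights outside `[0, 1.5]` are rejected.
#'
#' @param sleep_sig,cort_sig `forcing_signal` objects covering a common
#'   window.
#' @param p_S,p_C combination weights in `[0, 1.5]`.
#' @return A `forcing_signal`.
#' @export
combine_forcing <- function(sleep_sig, cort_sig, p_S, p_C) {
  check_weights(p_S, p_C)
  t_end <- min(max(sleep_sig$time_s), max(cort_sig$time_s))
  step <- min(min(diff(sleep_sig$time_s)), min(diff(cort_sig$time_s)))
  grid <- seq(0, t_end, by = step)
  vals <- p_S * eval_forcing(sleep_sig, grid) +
    p_C * eval_forcing(cort_sig, grid)
  forcing_signal(grid, vals, interp = "zoh")
}

#' Compress a forcing signal's timeline
#'
#' Rescales the time grid by `scale`, used for compressed simulation
#' configurations in which one clock hour is represented by
#' `sim_hour_s = 3600 * scale` simulated seconds. The network dynamics are
#' fast (seconds) relative to the forcing (hours), so event rates per
#' simulated second are insensitive to the compression.
#'
#' @param sig a `forcing_signal`.
#' @param scale timeline scale factor in (0, 1].
#' @return A `forcing_signal` on the compressed grid.
#' @export
compress_forcing <- function(sig, scale) {
  forcing_signal(sig$time_s * scale, sig$values, interp = sig$interp)
}
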