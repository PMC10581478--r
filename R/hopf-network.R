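#' @title Stochastic bistable brain-network model
#' @description The network model couples N nodes, each governed by the
#'   normal form of a subcritical Hopf bifurcation, so every node is
#'   bistable between a low-amplitude background state and a high-amplitude
#'   epileptiform oscillation. A slow excitability variable
#'   \eqn{\lambda_i(t)} relaxes towards \eqn{\lambda_{base} +
#'   \lambda_{ext}(t)} minus the ongoing activity \eqn{|z_i|^2}, so
#'   excursions self-terminate. Transitions are driven by white noise and
#'   by the external forcing; integration is Euler-Maruyama.
#' @name hopf_network
NULL

#' Default directed connected adjacency
#'
#' A directed ring `1 -> 2 -> ... -> n -> 1` with a reciprocal chord between
#' node 1 and the middle node (for `n >= 4`), giving a directed, weakly
#' connected binary graph with zero diagonal.
#'
#' @param n node count.
#' @return An `n x n` integer 0/1 matrix.
#' @export
default_adjacency <- function(n = 4) {
  if (n == 1) return(matrix(0L, 1, 1))
  A <- matrix(0L, n, n)
  A[cbind(seq_len(n), c(seq_len(n)[-1], 1L))] <- 1L
  if (n >= 4) {
    m <- n %/% 2 + 1L
    A[1, m] <- A[m, 1] <- 1L
  }
  A
}

#' Network model parameters
#'
#' Defaults are the model's standard operating point: `omega = 20` rad/s,
#' `beta = 0.35`, `alpha = 0.055`, `tau = 3` s, `lambda_base = 0.65`,
#' 4 nodes, `dt = 1e-3` s. Note that the Euler-Maruyama step size is part
#' of the operating definition of the model: the discretisation of the fast
#' rotation contributes an effective excitability offset of order
#' `omega^2 * dt / 2`, so event rates are only comparable between runs at
#' equal `dt`.
#'
#' @param n_nodes node count.
#' @param adjacency binary adjacency matrix, zero diagonal, weakly
#'   connected.
#' @param omega angular frequency of the epileptiform oscillation (rad/s).
#' @param beta diffusive coupling strength.
#' @param alpha noise amplitude.
#' @param tau excitability relaxation time (s).
#' @param lambda_base baseline excitability.
#' @param dt Euler-Maruyama step (s).
#' @return An object of class `hopf_network`.
#' @export
network_model <- function(n_nodes = 4, adjacency = default_adjacency(n_nodes),
                          omega = 20, beta = 0.35, alpha = 0.055, tau = 3,
                          lambda_base = 0.65, dt = 1e-3) {
  adjacency <- matrix(as.integer(adjacency), n_nodes, n_nodes)
  if (!all(adjacency %in% c(0L, 1L))) stopf("adjacency must be binary")
  if (any(diag(adjacency) != 0L)) stopf("adjacency must have zero diagonal")
  if (n_nodes > 1 && !weakly_connected(adjacency))
    stopf("adjacency must be weakly connected")
  if (omega <= 0 || tau <= 0 || dt <= 0) stopf("rate/time constants must be positive")
  if (alpha < 0 || beta < 0) stopf("alpha and beta must be non-negative")
  structure(list(n_nodes = as.integer(n_nodes), adjacency = adjacency,
                 omega = omega, beta = beta, alpha = alpha, tau = tau,
                 lambda_base = lambda_base, dt = dt),
            class = "hopf_network")
}

weakly_connected <- function(A) {
  U <- (A + t(A)) > 0
  seen <- logical(nrow(A)); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(U[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.hopf_network <- function(x, ...) {
  cat(sprintf(
    "<hopf_network> %d nodes, omega=%g beta=%g alpha=%g tau=%g lambda_base=%g dt=%g\n",
    x$n_nodes, x$omega, x$beta, x$alpha, x$tau, x$lambda_base, x$dt))
  invisible(x)
}

#' Deterministic drift of the node states
#'
#' \deqn{f_i = (\lambda_i - 1 + i\omega) z_i + 2 z_i |z_i|^2 - z_i |z_i|^4
#'   + \beta \sum_j A_{ij} (z_j - z_i)}
#'
#' @param z complex state vector (one entry per node).
#' @param lam excitability per node.
#' @param model a `hopf_network`.
#' @return Complex drift vector.
#' @export
hopf_drift <- function(z, lam, model) {
  r2 <- Mod(z)^2
  coupling <- model$beta * (as.vector(model$adjacency %*% z) -
                              rowSums(model$adjacency) * z)
  (lam - 1 + 1i * model$omega) * z + 2 * z * r2 - z * r2^2 + coupling
}

#' One Euler-Maruyama step
#'
#' Advances `z` by drift plus `alpha * (xi_re + i xi_im) * sqrt(dt)` and then
#' relaxes the excitability: `lam <- lam + dt/tau * (lambda_base +
#' lambda_ext - lam - |z|^2)` using the updated amplitude.
#'
#' @param state list with complex `z` and numeric `lam`.
#' @param forcing_value \eqn{\lambda_{ext}} at this step (scalar or per
#'   node).
#' @param model a `hopf_network`.
#' @param noise complex standard-normal increments per node (default 0 for
#'   deterministic stepping).
#' @return Updated state list.
#' @export
hopf_step <- function(state, forcing_value, model,
                      noise = complex(real = rep(0, model$n_nodes),
                                      imaginary = rep(0, model$n_nodes))) {
  dt <- model$dt
  z <- state$z + hopf_drift(state$z, state$lam, model) * dt +
    model$alpha * noise * sqrt(dt)
  lam <- state$lam + dt / model$tau *
    (model$lambda_base + forcing_value - state$lam - Mod(z)^2)
  if (any(!is.finite(c(Re(z), Im(z), lam))))
    stopf("non-finite state after step (node %d)",
          which(!is.finite(Re(z) + Im(z) + lam))[1])
  list(z = z, lam = lam)
}

#' Simulate the network under a forcing signal
#'
#' Full Euler-Maruyama trajectory over `[0, duration_s]` preceded by a
#' discarded burn-in (the forcing is wrapped circularly into the burn-in
#' window). Events are excursions of each node's amplitude `|z_i|` through
#' a hysteresis detector (onset at `onset_thr`, reset at `offset_thr`);
#' pooled event onsets closer than `min_separation_s` count once.
#'
#' @param model a `hopf_network`.
#' @param forcing a `forcing_signal` covering `[0, duration_s]`.
#' @param duration_s simulated duration (s).
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @param record_traces keep thinned state traces (every `trace_stride`
#'   steps).
#' @param burn_in_s discarded spin-up time (s).
#' @param onset_thr,offset_thr,min_separation_s event detector settings.
#' @param trace_stride thinning stride for traces.
#' @return An object of class `hopf_sim`: per-node onset times
#'   (`events_by_node`), pooled merged onsets (`event_times`), `seed`, the
#'   detector settings, and optional traces.
#' @export
simulate_hopf <- function(model, forcing, duration_s, seed = NULL,
                          record_traces = FALSE, burn_in_s = 60,
                          onset_thr = 1.0, offset_thr = 0.5,
                          min_separation_s = 1.0, trace_stride = 100L) {
  if (onset_thr <= offset_thr || offset_thr <= 0)
    stopf("need onset_thr > offset_thr > 0 (hysteresis)")
  if (max(forcing$time_s) < duration_s)
    stopf("forcing grid (%.0f s) does not cover the simulation window (%.0f s)",
          max(forcing$time_s), duration_s)

  # wrap the forcing tail into the burn-in window so spin-up sees the same
  # physiology as the end of the (circular) day
  period <- max(forcing$time_s)
  ft <- forcing$time_s
  fv <- forcing$values
  if (burn_in_s > 0) {
    pre <- ft >= period - burn_in_s & ft < period
    ft <- c(ft[pre] - period, ft)
    fv <- rbind(fv[pre, , drop = FALSE], fv)
  }

  res <- with_seed(seed, {
    hopf_simulate_cpp(model$n_nodes, model$adjacency, model$omega,
                      model$beta, model$alpha, model$tau, model$lambda_base,
                      model$dt, ft, fv, -burn_in_s, duration_s,
                      onset_thr, offset_thr, record_traces,
                      as.integer(trace_stride))
  })

  by_node <- lapply(res$events, function(tt) merge_onsets(tt, min_separation_s))
  pooled <- merge_onsets(sort(unlist(by_node)), min_separation_s)
  out <- list(events_by_node = by_node,
              event_times = pooled,
              duration_s = duration_s,
              seed = seed,
              onset_thr = onset_thr, offset_thr = offset_thr,
              min_separation_s = min_separation_s,
              final_state = list(z = complex(real = res$final_re,
                                             imaginary = res$final_im),
                                 lam = res$final_lambda))
  if (record_traces) {
    out$trace <- list(time_s = res$trace_time,
                      re = res$trace_re, im = res$trace_im,
                      lambda = res$trace_lambda)
  }
  structure(out, class = "hopf_sim")
}

#' @export
print.hopf_sim <- function(x, ...) {
  cat(sprintf("<hopf_sim> %.0f s, %d pooled events (%s per node)\n",
              x$duration_s, length(x$event_times),
              paste(lengths(x$events_by_node), collapse = "/")))
  invisible(x)
}

# Drop onsets closer than min_sep to the previously kept onset.
merge_onsets <- function(t, min_sep) {
  if (!length(t)) return(numeric(0))
  t[c(TRUE, diff(t) > min_sep)]
}

#' Hysteresis event detection on an amplitude series
#'
#' An event starts at an upward crossing of `onset_thr` while the node is in
#' the background state; the state resets at the next downward crossing of
#' `offset_thr`. Onsets closer than `min_separation_s` are merged.
#'
#' @param amplitude numeric series of `|z|`.
#' @param time_s sample times (or a scalar step, expanded from 0).
#' @param onset_thr,offset_thr hysteresis thresholds (`onset > offset > 0`).
#' @param min_separation_s merge window for nearby onsets.
#' @return Numeric vector of event onset times.
#' @export
detect_events <- function(amplitude, time_s, onset_thr = 1.0,
                          offset_thr = 0.5, min_separation_s = 1.0) {
  if (onset_thr <= offset_thr || offset_thr <= 0)
    stopf("need onset_thr > offset_thr > 0 (hysteresis)")
  if (length(time_s) == 1L)
    time_s <- (seq_along(amplitude) - 1L) * time_s
  in_event <- FALSE
  onsets <- numeric(0)
  for (i in seq_along(amplitude)) {
    if (!in_event && amplitude[i] >= onset_thr) {
      in_event <- TRUE
      onsets <- c(onsets, time_s[i])
    } else if (in_event && amplitude[i] <= offset_thr) {
      in_event <- FALSE
    }
  }
  merge_onsets(onsets, min_separation_s)
}

#' Bin simulated events into 24 hourly counts
#'
#' Event times (seconds of simulation) are mapped to clock hours via
#' `clock_offset_h` and counted into half-open hourly bins `[h, h+1)`.
#' `seconds_per_hour` supports compressed simulation timelines where one
#' clock hour is represented by fewer simulated seconds.
#'
#' @param sim a `hopf_sim` (or a numeric vector of event times in seconds).
#' @param clock_offset_h clock hour corresponding to simulation time 0.
#' @param seconds_per_hour simulated seconds per clock hour (default 3600).
#' @return Integer vector of 24 counts.
#' @export
bin_events <- function(sim, clock_offset_h = 0, seconds_per_hour = 3600) {
  t <- if (inherits(sim, "hopf_sim")) sim$event_times else as.numeric(sim)
  h <- floor((t / seconds_per_hour + clock_offset_h) %% 24)
  as.integer(tabulate(h + 1L, nbins = 24L))
}
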