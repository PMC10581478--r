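#' @title Circadian ED distribution analysis
#' @description Hourly rate construction, pairwise correlation, k-means
#'   phenotype clustering with Calinski-Harabasz model selection, sleep
#'   alignment, the sleep-fraction statistic, and circular density peak
#'   detection.
#' @name ed_cohort
NULL

#' Hourly (or arbitrary-width) event counts for one subject
#'
#' Events are optionally re-anchored so that `t = 0` corresponds to the
#' subject's sleep onset or offset, then counted into half-open bins of
#' `bin_width_min` minutes over the 24-h circle. When 1440 is not a
#' multiple of the bin width the last bin is short (flagged via the
#' `short_last_bin` attribute).
#'
#' @param record an `ed_record`.
#' @param bin_width_min bin width in minutes (default 60).
#' @param anchor one of `"clock"`, `"sleep_onset"`, `"sleep_offset"`.
#' @return Integer count vector with attributes `bin_width_min`, `anchor`,
#'   `short_last_bin`.
#' @export
hourly_counts <- function(record, bin_width_min = 60,
                          anchor = c("clock", "sleep_onset", "sleep_offset")) {
  anchor <- match.arg(anchor)
  if (bin_width_min <= 0) stopf("bin_width_min must be positive")
  t <- record$event_times
  t <- switch(anchor,
              clock = t,
              sleep_onset = wrap24(t - record$sleep_onset_clock),
              sleep_offset = wrap24(t - record$sleep_offset_clock))
  n_bins <- ceiling(1440 / bin_width_min)
  idx <- pmin(floor(t * 60 / bin_width_min), n_bins - 1L) + 1L
  counts <- as.integer(tabulate(idx, nbins = n_bins))
  structure(counts, bin_width_min = bin_width_min, anchor = anchor,
            short_last_bin = (1440 %% bin_width_min) != 0)
}

#' Per-subject normalised hourly rates
#'
#' Each subject's count vector is divided by their total event count, so
#' rows sum to one; the cohort-level curve is the across-subject mean of
#' the rows rescaled to unit sum. Subjects with zero events are excluded
#' (with a message).
#'
#' @param counts matrix (subjects x bins), list of count vectors, or list
#'   of `ed_record` (counted at the clock anchor).
#' @param subject_ids optional identifiers.
#' @return An object of class `cohort_rates`: `subject_ids`, `rates`
#'   (rows sum to 1), `cohort_curve` (unit sum), `excluded`.
#' @export
normalize_rates <- function(counts, subject_ids = NULL) {
  if (is.list(counts) && length(counts) && inherits(counts[[1]], "ed_record")) {
    if (is.null(subject_ids))
      subject_ids <- vapply(counts, `[[`, "", "subject_id")
    counts <- t(vapply(counts, hourly_counts, integer(24)))
  } else if (is.list(counts)) {
    counts <- do.call(rbind, counts)
  }
  counts <- as.matrix(counts)
  if (is.null(subject_ids))
    subject_ids <- rownames(counts) %||% sprintf("s%03d", seq_len(nrow(counts)))
  tot <- rowSums(counts)
  if (all(tot == 0)) stopf("every subject has zero events")
  drop <- tot == 0
  if (any(drop))
    message(sprintf("excluding %d subject(s) with zero events: %s",
                    sum(drop), paste(subject_ids[drop], collapse = ", ")))
  rates <- counts[!drop, , drop = FALSE] / tot[!drop]
  cohort <- colMeans(rates)
  cohort <- cohort / sum(cohort)
  structure(list(subject_ids = subject_ids[!drop], rates = rates,
                 cohort_curve = cohort, normalization = "per_subject",
                 excluded = subject_ids[drop]),
            class = "cohort_rates")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise correlation of hourly rate profiles
#'
#' Zero-lag Pearson correlation between every pair of subjects' normalised
#' rate vectors. Pairs involving a constant profile are assigned similarity
#' 0 (with a message); the diagonal is 1.
#'
#' @param rates a `cohort_rates` or a subjects-x-bins matrix.
#' @return Symmetric correlation matrix with unit diagonal, class
#'   `ed_correlation`.
#' @export
correlation_matrix <- function(rates) {
  X <- if (inherits(rates, "cohort_rates")) rates$rates else as.matrix(rates)
  if (nrow(X) < 2) stopf("need at least 2 subjects")
  constant <- apply(X, 1, function(r) var(r) == 0)
  C <- suppressWarnings(cor(t(X)))
  if (any(constant)) {
    message(sprintf("%d constant profile(s): correlations set to 0",
                    sum(constant)))
    C[constant, ] <- 0
    C[, constant] <- 0
  }
  diag(C) <- 1
  if (inherits(rates, "cohort_rates"))
    dimnames(C) <- list(rates$subject_ids, rates$subject_ids)
  structure(C, class = c("ed_correlation", "matrix"))
}

# Calinski-Harabasz index from a kmeans fit
ch_index <- function(km, n) {
  k <- length(km$size)
  W <- km$tot.withinss
  B <- km$betweenss
  if (W <= .Machine$double.eps * max(1, B)) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Cluster subjects by their correlation profiles
#'
#' Each subject's feature vector is their row of the correlation matrix.
#' k-means (multiple random restarts) is run for every candidate `k`; the
#' Calinski-Harabasz criterion selects `k_optimal` (ties broken toward
#' smaller k). A perfectly separable cohort (zero within-cluster scatter)
#' yields an infinite criterion value and wins directly.
#'
#' @param C an `ed_correlation` (or square similarity matrix).
#' @param k_range candidate cluster counts (default 2:10).
#' @param n_replicates random restarts per k (default 100).
#' @param seed integer seed.
#' @return An object of class `ed_clusters`: `labels`, `k_optimal`,
#'   `criterion_curve`, `seed`.
#' @export
cluster_subjects <- function(C, k_range = 2:10, n_replicates = 100,
                             seed = NULL) {
  C <- unclass(C)
  n <- nrow(C)
  if (max(k_range) >= n) stopf("k_range maximum must be below n_subjects")
  if (all(abs(sweep(C, 2, C[1, ])) < 1e-12))
    stopf("no cluster structure: all subjects have identical profiles")
  n_distinct <- nrow(unique(C))
  with_seed(seed, {
    fits <- lapply(k_range, function(k) {
      if (k > n_distinct) return(NULL)  # k-means undefined beyond this
      suppressWarnings(kmeans(C, centers = k, nstart = n_replicates,
                              iter.max = 100))
    })
    crit <- vapply(fits, function(f)
      if (is.null(f)) -Inf else ch_index(f, n), 0)
    best <- which(crit == max(crit))[1]  # ties toward smaller k
    structure(list(labels = fits[[best]]$cluster,
                   k_optimal = k_range[best],
                   criterion_curve = stats::setNames(crit, k_range),
                   seed = seed),
              class = "ed_clusters")
  })
}

#' @export
print.ed_clusters <- function(x, ...) {
  cat(sprintf("<ed_clusters> k = %d (CH criterion), sizes: %s\n",
              x$k_optimal, paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Fraction of EDs occurring during sleep
#'
#' For each group, the mean over subjects of the fraction of their events
#' falling inside their own sleep window (half-open, wrapping midnight).
#' Subjects with zero events are excluded with a warning.
#'
#' @param records list of `ed_record`.
#' @param groups optional group label per record (defaults to the records'
#'   `group_label`, or a single group).
#' @return Named numeric vector of per-group fractions, with the per-subject
#'   fractions attached as attribute `per_subject`.
#' @export
sleep_fraction <- function(records, groups = NULL) {
  if (is.null(groups))
    groups <- vapply(records, function(r) r$group_label %||% 1L, 1L)
  frac <- vapply(records, function(r) {
    if (!length(r$event_times)) return(NA_real_)
    mean(in_sleep_window(r$event_times, r$sleep_onset_clock,
                         r$sleep_offset_clock))
  }, 0)
  if (anyNA(frac)) {
    warnf("excluding %d subject(s) with zero events", sum(is.na(frac)))
  }
  out <- tapply(frac, groups, mean, na.rm = TRUE)
  structure(as.vector(out), names = names(out), per_subject = frac)
}

#' Peaks of the circular event-time density
#'
#' Gaussian kernel density of pooled event times on the 24-h circle
#' (computed on a tripled unwrapped sample); local maxima are kept when
#' their prominence — height above the higher of the two flanking minima —
#' exceeds `prominence_floor`, and returned sorted by height.
#'
#' @param event_times pooled event times, clock hours (>= 10 events).
#' @param bandwidth_h kernel bandwidth in hours (> 0).
#' @param prominence_floor minimal prominence in density units (the uniform
#'   density is 1/24 ~ 0.042).
#' @param n_grid evaluation grid size.
#' @return `data.frame` with columns `location`, `height`, `prominence`.
#' @export
density_peaks <- function(event_times, bandwidth_h = 1,
                          prominence_floor = 0.02, n_grid = 512) {
  if (bandwidth_h <= 0) stopf("bandwidth must be positive")
  if (length(event_times) < 10) stopf("need at least 10 events")
  t <- wrap24(event_times)
  d <- density(c(t - 24, t, t + 24), bw = bandwidth_h, from = 0, to = 24,
               n = n_grid + 1)
  x <- d$x[-(n_grid + 1)]
  y <- 3 * d$y[-(n_grid + 1)]  # each copy carries 1/3 of the mass

  nxt <- c(seq_len(n_grid)[-1], 1L)
  prv <- c(n_grid, seq_len(n_grid)[-n_grid])
  is_peak <- y > y[prv] & y >= y[nxt]
  peaks <- which(is_peak)
  if (!length(peaks)) return(data.frame(location = numeric(0),
                                        height = numeric(0),
                                        prominence = numeric(0)))
  # flanking minima between consecutive peaks (circular)
  prom <- vapply(peaks, function(p) {
    others <- setdiff(peaks, p)
    if (!length(others)) return(y[p] - min(y))
    # walk to the nearest minima on each side
    left <- p; repeat {
      l2 <- prv[left]
      if (y[l2] > y[left] || l2 == p) break
      left <- l2
    }
    right <- p; repeat {
      r2 <- nxt[right]
      if (y[r2] > y[right] || r2 == p) break
      right <- r2
    }
    y[p] - max(y[left], y[right])
  }, 0)
  keep <- prom >= prominence_floor
  out <- data.frame(location = x[peaks][keep], height = y[peaks][keep],
                    prominence = prom[keep])
  out[order(-out$height), , drop = FALSE]
}
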