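#' @title CSV interchange
#' @description Plain-text readers and writers for the pipeline's
#'   interchange formats: per-event ED tables with sleep windows,
#'   per-epoch hypnograms, 10-min cortisol profiles, and forcing signals.
#' @name io
NULL

#' Read an ED cohort from CSV
#'
#' `events_csv` has one row per event (`subject_id, event_time_h`) or one
#' row per subject-hour (`subject_id, hour, count`); `sleep_csv` has one
#' row per subject (`subject_id, sleep_onset_h, sleep_offset_h`).
#'
#' @param events_csv,sleep_csv file paths.
#' @return List of [ed_record()].
#' @export
read_ed_cohort <- function(events_csv, sleep_csv) {
  ev <- read.csv(events_csv)
  sl <- read.csv(sleep_csv)
  if (!all(c("subject_id", "sleep_onset_h", "sleep_offset_h") %in% names(sl)))
    stopf("sleep CSV needs subject_id, sleep_onset_h, sleep_offset_h")
  lapply(seq_len(nrow(sl)), function(i) {
    id <- sl$subject_id[i]
    times <- if ("event_time_h" %in% names(ev)) {
      ev$event_time_h[ev$subject_id == id]
    } else if (all(c("hour", "count") %in% names(ev))) {
      sub <- ev[ev$subject_id == id, ]
      rep(sub$hour + 0.5, sub$count)  # bin centres
    } else stopf("events CSV needs event_time_h or hour+count columns")
    ed_record(times, sl$sleep_onset_h[i], sl$sleep_offset_h[i],
              subject_id = as.character(id))
  })
}

#' Write an ED cohort to CSV
#'
#' @param records list of `ed_record`.
#' @param events_csv,sleep_csv output paths.
#' @return Invisibly, the two paths.
#' @export
write_ed_cohort <- function(records, events_csv, sleep_csv) {
  ev <- do.call(rbind, lapply(records, function(r)
    if (length(r$event_times))
      data.frame(subject_id = r$subject_id, event_time_h = r$event_times)
    else NULL))
  sl <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id,
               sleep_onset_h = r$sleep_onset_clock,
               sleep_offset_h = r$sleep_offset_clock)))
  write.csv(ev, events_csv, row.names = FALSE)
  write.csv(sl, sleep_csv, row.names = FALSE)
  invisible(c(events_csv, sleep_csv))
}

#' Read hypnograms from CSV
#'
#' Columns: `subject_id, epoch_index, stage, sleep_onset_h, epoch_s`.
#'
#' @param path file path.
#' @return List of [hypnogram()].
#' @export
read_hypnograms <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$epoch_index), ]
    ep <- sub$epoch_s[1]
    onset <- sub$sleep_onset_h[1]
    hypnogram(sub$stage, onset,
              wrap24(onset + nrow(sub) * ep / 3600),
              epoch_s = ep, subject_id = as.character(sub$subject_id[1]))
  })
}

#' Write hypnograms to CSV
#' @param hypnograms list of `hypnogram`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_hypnograms <- function(hypnograms, path) {
  df <- do.call(rbind, lapply(hypnograms, function(h)
    data.frame(subject_id = h$subject_id,
               epoch_index = seq_along(h$stages),
               stage = h$stages,
               sleep_onset_h = h$sleep_onset_clock,
               epoch_s = h$epoch_s)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read cortisol profiles from CSV
#'
#' Columns: `subject_id, time_min, concentration` (145 rows per subject).
#'
#' @param path file path.
#' @return List of [cort_profile()].
#' @export
read_cort_profiles <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$time_min), ]
    cort_profile(sub$concentration, subject_id = as.character(sub$subject_id[1]),
                 sample_times_min = sub$time_min)
  })
}

#' Write cortisol profiles to CSV
#' @param profiles list of `cort_profile`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_cort_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, time_min = p$sample_times_min,
               concentration = p$concentrations)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a forcing signal to CSV
#'
#' Two columns: `time_s, lambda_ext` (one extra column per node for
#' per-node signals).
#'
#' @param sig a `forcing_signal`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_forcing <- function(sig, path) {
  df <- data.frame(time_s = sig$time_s)
  if (ncol(sig$values) == 1L) df$lambda_ext <- sig$values[, 1]
  else for (j in seq_len(ncol(sig$values)))
    df[[sprintf("lambda_ext_node%d", j)]] <- sig$values[, j]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
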