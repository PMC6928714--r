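# Dose-time (DT) and effect-time (ET) windows around the first daily dose
# and their weekly aggregate statistics.

#' Extract the dose-time window for one dose
#'
#' The DT window is the 5 grid epochs (10 min) centered on the epoch
#' containing the acknowledgement of the first reminder of the day, minus
#' inactive and off-wrist epochs. An empty result marks that day's DT as
#' unavailable.
#'
#' @param recording a `pkg_recording`.
#' @param dose one row of the recording's `dose_events` (needs an
#'   acknowledgement), or a nominal acknowledgement time in minutes.
#' @param labels activity labels from [label_activity()].
#' @param n_epochs window size in epochs (odd, default 5).
#' @return integer vector of usable epoch indices (possibly empty).
#' @export
extract_dt <- function(recording, dose, labels, n_epochs = 5) {
  ack <- if (is.numeric(dose)) dose else dose$acknowledgement_min
  window_epoch_indices(recording, ack, labels, n_epochs)
}

window_epoch_indices <- function(recording, center_min, labels, n_epochs = 5) {
  epochs <- recording$epochs
  step <- EPOCH_MINUTES
  t0 <- epochs$timestamp_min[1L]
  tmax <- epochs$timestamp_min[nrow(epochs)]
  if (is.na(center_min) || center_min < t0 || center_min > tmax + step) {
    stopf("window center %s lies outside the recording span", center_min)
  }
  h <- (n_epochs - 1L) %/% 2L
  anchor <- floor((center_min - t0) / step) * step + t0
  starts <- anchor + step * seq(-h, h)
  idx <- match(starts, epochs$timestamp_min)
  idx <- idx[!is.na(idx)]
  idx[labels[idx] == "active"]
}

#' Locate the effect time on the smoothed weekly series
#'
#' The effect time is the offset of maximal levodopa effect -- the
#' minimum of the dose-aligned smoothed weekly BKS series -- within the
#' closed search window (default 46-90 min after acknowledgement), taking
#' the earliest offset on ties.
#'
#' @param weekly data frame from [smoothed_weekly_series()].
#' @param search_start,search_end search window bounds in minutes.
#' @return the effect-time offset in minutes, or `NA` when the series is
#'   entirely missing inside the window.
#' @export
find_et <- function(weekly, search_start = 46, search_end = 90) {
  win <- weekly[weekly$offset_min >= search_start &
                weekly$offset_min <= search_end, , drop = FALSE]
  ok <- !is.na(win$value)
  if (!any(ok)) return(NA_real_)
  win <- win[ok, , drop = FALSE]
  win$offset_min[which.min(win$value)]
}

#' Per-day effect-time windows at a fixed offset
#'
#' The effect time is located once per recording on the weekly series and
#' reused for every day: for each alignment anchor the window is the 5
#' epochs centered at `anchor + et_offset`, filtered as for DT.
#'
#' @param recording a `pkg_recording`.
#' @param align_times per-day alignment minutes (dose acknowledgements, or
#'   nominal dose times for controls).
#' @param et_offset minutes from acknowledgement, from [find_et()].
#' @param labels activity labels.
#' @param n_epochs window size (default 5).
#' @return list of integer index vectors, one per day.
#' @export
extract_et <- function(recording, align_times, et_offset, labels,
                       n_epochs = 5) {
  step <- EPOCH_MINUTES
  t0 <- recording$epochs$timestamp_min[1L]
  lapply(align_times, function(a) {
    anchor <- floor((a - t0) / step) * step + t0
    window_epoch_indices(recording, anchor + et_offset, labels, n_epochs)
  })
}

#' Weekly aggregate of window features
#'
#' Pools the usable epochs of all per-day windows (up to 5 per day, so up
#' to 30 for a 6-day recording) and reports the mean and sample standard
#' deviation of each feature over the pooled epochs.
#'
#' @param windows list of per-day epoch index vectors.
#' @param feature_table data frame from [featurize()] evaluated at (at
#'   least) those epochs, carrying a `timestamp_min` column.
#' @param timestamps epoch timestamps of the recording, used to map window
#'   indices onto `feature_table` rows.
#' @return list with `n_epochs_total`, `per_day_n`, `weekly_mean` and
#'   `weekly_sd` (named numeric vectors over feature columns), or `NULL`
#'   when no usable epoch remains.
#' @export
weekly_aggregate <- function(windows, feature_table, timestamps) {
  idx <- unlist(windows, use.names = FALSE)
  if (!length(idx)) return(NULL)
  rows <- match(timestamps[idx], feature_table$timestamp_min)
  if (anyNA(rows)) stopf("feature table does not cover all window epochs")
  feats <- feature_table[rows, setdiff(names(feature_table),
                                       c("timestamp_min", "usable")),
                         drop = FALSE]
  list(n_epochs_total = length(idx),
       per_day_n = vapply(windows, length, integer(1)),
       weekly_mean = vapply(feats, mean, numeric(1)),
       weekly_sd = vapply(feats, stats::sd, numeric(1)))
}

#' Dose and effect windows for a whole recording
#'
#' Convenience wrapper: computes activity labels, the dose-aligned weekly
#' series, the effect-time offset, and the per-day DT and ET windows.
#' Controls (or `nominal_dt` given) are aligned on a nominal dose time
#' instead of dose acknowledgements.
#'
#' @param recording a `pkg_recording`.
#' @param labels optional precomputed activity labels.
#' @param search_start,search_end ET search window, minutes.
#' @param nominal_dt optional clock minute (from midnight) used as the
#'   daily alignment anchor when there are no dose events.
#' @return list with `labels`, `align_times`, `weekly`, `et_offset`,
#'   `dt_windows`, `et_windows`.
#' @export
dose_windows <- function(recording, labels = NULL, search_start = 46,
                         search_end = 90, nominal_dt = NULL) {
  labels <- labels %||% label_activity(recording)
  de <- recording$dose_events
  if (!is.null(de) && any(de$first_of_day & !is.na(de$acknowledgement_min))) {
    align <- de$acknowledgement_min[de$first_of_day &
                                    !is.na(de$acknowledgement_min)]
  } else if (!is.null(nominal_dt)) {
    t0 <- recording$epochs$timestamp_min[1L]
    tmax <- recording$epochs$timestamp_min[nrow(recording$epochs)]
    days <- seq(floor(t0 / 1440), floor(tmax / 1440))
    align <- days * 1440 + nominal_dt
    align <- align[align >= t0 & align <= tmax]
  } else {
    stopf("recording %s has no dose events and no nominal dose time",
          recording$subject_id)
  }
  weekly <- smoothed_weekly_series(recording, align_times = align,
                                   labels = labels)
  et_offset <- find_et(weekly, search_start, search_end)
  dt_windows <- lapply(align, function(a) {
    extract_dt(recording, a, labels)
  })
  et_windows <- if (is.na(et_offset)) {
    rep(list(integer(0)), length(align))
  } else {
    extract_et(recording, align, et_offset, labels)
  }
  list(labels = labels, align_times = align, weekly = weekly,
       et_offset = et_offset, dt_windows = dt_windows,
       et_windows = et_windows)
}
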