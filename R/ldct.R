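# Per-subject levodopa-response estimation: severity at dose time versus
# effect time, the absolute and percentage response, and the three
# exclusion flags (uncertain zone, already ON, excess variability).

#' Uncertain zone for the UPDRS-measured response
#'
#' Absolute OFF-to-ON improvements inside the zone (defaults 11-14, a
#' 4-point band centered on one severity-level increment) are neither
#' clearly meaningful nor clearly insignificant.
#'
#' @param lower,upper zone bounds in UPDRS III points.
#' @return list of class `uncertain_zone` with `lower`, `upper` and
#'   `width` (number of integer scores inside the zone).
#' @export
uncertain_zone <- function(lower = 11, upper = 14) {
  if (lower > upper) stopf("uncertain zone: lower must be <= upper")
  structure(list(lower = lower, upper = upper, width = upper - lower + 1),
            class = "uncertain_zone")
}

#' Classify a UPDRS response as meaningful, uncertain or insignificant
#'
#' @param abs_delta_updrs absolute OFF-to-ON improvement in (adjusted)
#'   UPDRS III points; vectorized.
#' @param zone an [uncertain_zone()].
#' @return character vector: `"meaningful"` (above the zone),
#'   `"uncertain"` (inside it) or `"insignificant"` (below it).
#' @export
classify_lr <- function(abs_delta_updrs, zone = uncertain_zone()) {
  ifelse(abs_delta_updrs > zone$upper, "meaningful",
         ifelse(abs_delta_updrs >= zone$lower, "uncertain", "insignificant"))
}

#' Mean severity over a pool of window epochs
#'
#' Per-epoch severity predictions over all usable dose-time (or
#' effect-time) epochs pooled across days, averaged arithmetically.
#'
#' @param model a `severity_model`.
#' @param feature_table features at the pooled epochs ([featurize()]).
#' @return list with `mean`, `sd` (sample SD of the per-epoch levels),
#'   `n`, and the per-epoch predictions, or `NULL` when no usable epoch
#'   with complete features remains.
#' @export
estimate_mfsl_at <- function(model, feature_table) {
  pred <- predict_epoch_mfsl(model, feature_table)
  pred <- pred[!is.na(pred)]
  if (!length(pred)) return(NULL)
  list(mean = mean(pred), sd = stats::sd(pred), n = length(pred),
       epoch_mfsl = pred)
}

#' Absolute and percentage levodopa response
#'
#' @param mfsl_dt,mfsl_et mean severity at dose time and effect time.
#' @return list with `abs_delta_pkg = mfsl_dt - mfsl_et` and
#'   `pct_delta_pkg = abs / dt * 100` (`NA` when `mfsl_dt` is 0: a
#'   subject with no measurable dose-time severity has no defined
#'   percentage improvement).
#' @export
compute_lr <- function(mfsl_dt, mfsl_et) {
  abs_delta <- mfsl_dt - mfsl_et
  pct <- if (mfsl_dt > 0) abs_delta / mfsl_dt * 100 else NA_real_
  list(abs_delta_pkg = abs_delta, pct_delta_pkg = pct)
}

#' Flag subjects whose morning severity looks already treated
#'
#' A subject is flagged "already ON" when the dose-time severity is in
#' the treated range (below level 3) while the model finds substantially
#' worse severity later in the day: the mean plus one standard deviation
#' of the per-epoch severity from `daytime_start_offset` minutes after the
#' first dose until `daytime_end_minute` (pooled over days) exceeds the
#' dose-time severity by more than one level.
#'
#' @param daytime list with `mean`, `sd` over the daytime pool
#'   (from [estimate_mfsl_at()]).
#' @param mfsl_dt dose-time mean severity.
#' @param gate_level treated-range gate (default 3).
#' @param margin_levels required exceedance (default 1).
#' @return logical, or `NA` when the daytime pool was unavailable.
#' @export
flag_already_on <- function(daytime, mfsl_dt, gate_level = 3,
                            margin_levels = 1) {
  if (is.null(daytime) || is.na(mfsl_dt)) return(NA)
  if (mfsl_dt >= gate_level) return(FALSE)
  sdv <- if (is.na(daytime$sd)) 0 else daytime$sd
  (daytime$mean + sdv) > (mfsl_dt + margin_levels)
}

#' Flag excess day-to-day variability
#'
#' Amplitude: the standard deviation of the per-epoch severity over the
#' pooled dose-time epochs and over the pooled effect-time epochs must
#' both exceed one level. Latency: the per-day trough latencies of the
#' dose-aligned smoothed BKS series inside the search window must have a
#' standard deviation above `latency_sd_min` minutes (a quarter of the
#' 44-minute search window by default).
#'
#' @param dt_est,et_est [estimate_mfsl_at()] results for DT and ET pools.
#' @param per_day_latency per-day trough latencies in minutes.
#' @param sd_threshold amplitude SD threshold in levels (default 1).
#' @param latency_sd_min latency SD threshold in minutes (default 11).
#' @return list with logicals `variable_amplitude`, `variable_latency`
#'   (`NA` where the inputs are insufficient).
#' @export
flag_variability <- function(dt_est, et_est, per_day_latency = NULL,
                             sd_threshold = 1, latency_sd_min = 11) {
  amp <- NA
  if (!is.null(dt_est) && !is.null(et_est) &&
      dt_est$n >= 2 && et_est$n >= 2) {
    amp <- dt_est$sd > sd_threshold && et_est$sd > sd_threshold
  }
  lat <- NA
  lats <- per_day_latency[!is.na(per_day_latency)]
  if (length(lats) >= 2) lat <- stats::sd(lats) > latency_sd_min
  list(variable_amplitude = amp, variable_latency = lat)
}

# Per-day trough latency: within-day argmin of the day's dose-aligned
# smoothed BKS inside the search window.
per_day_trough_latency <- function(recording, align_times, labels,
                                   search_start = 46, search_end = 90,
                                   smooth_window = 9) {
  vapply(align_times, function(a) {
    wk <- smoothed_weekly_series(recording, align_times = a,
                                 labels = labels,
                                 offsets = seq(search_start - 6,
                                               search_end + 6, by = 2),
                                 smooth_window = smooth_window)
    find_et(wk, search_start, search_end)
  }, numeric(1))
}

#' Run the instrumented levodopa challenge on one recording
#'
#' Assembles the per-subject result: severity at dose time and effect
#' time, the absolute and percentage response, the clinical response (when
#' UPDRS III labels are present) and the three exclusion flags. Controls
#' are processed with a nominal 10:00 dose time and zero UPDRS III.
#'
#' @param recording a `pkg_recording`.
#' @param model a trained `severity_model`.
#' @param search_start,search_end ET search window, minutes.
#' @param control_dt_minute controls' nominal dose-time clock minute
#'   (default 600 = 10:00).
#' @param daytime_end_minute end of the daytime span for the already-ON
#'   rule (default 1080 = 18:00).
#' @param zone an [uncertain_zone()].
#' @return one-row data frame (`ldct_result`): `subject_id`, `group`,
#'   `mfsl_dt`, `mfsl_et`, `abs_delta_pkg`, `pct_delta_pkg`,
#'   `abs_delta_updrs`, `pct_delta_updrs`, `classification`, the four
#'   flags, `et_latency_min`, `n_dt_epochs`, `n_et_epochs` and a
#'   `reason` code (`"ok"`, `"DT unavailable"`, `"ET unavailable"`).
#' @export
run_ldct <- function(recording, model, search_start = 46, search_end = 90,
                     control_dt_minute = 600, daytime_end_minute = 1080,
                     zone = uncertain_zone()) {
  labels <- label_activity(recording)
  dw <- dose_windows(recording, labels = labels,
                     search_start = search_start, search_end = search_end,
                     nominal_dt = if (recording$group == "control")
                       control_dt_minute)
  dt_idx <- unlist(dw$dt_windows, use.names = FALSE)
  et_idx <- unlist(dw$et_windows, use.names = FALSE)
  feat_at <- function(idx) {
    featurize(recording, at = idx, labels = labels, features = "selected")
  }
  dt_est <- if (length(dt_idx)) estimate_mfsl_at(model, feat_at(dt_idx))
  et_est <- if (length(et_idx)) estimate_mfsl_at(model, feat_at(et_idx))

  res <- data.frame(subject_id = recording$subject_id,
                    group = recording$group,
                    mfsl_dt = NA_real_, mfsl_et = NA_real_,
                    abs_delta_pkg = NA_real_, pct_delta_pkg = NA_real_,
                    abs_delta_updrs = NA_real_, pct_delta_updrs = NA_real_,
                    classification = NA_character_,
                    flag_uncertain = NA, flag_already_on = NA,
                    flag_variable_amplitude = NA, flag_variable_latency = NA,
                    et_latency_min = dw$et_offset,
                    n_dt_epochs = length(dt_idx),
                    n_et_epochs = length(et_idx), reason = "ok")

  # clinical response
  if (recording$group == "control") {
    res$abs_delta_updrs <- 0
    res$pct_delta_updrs <- NA_real_
  } else if (!is.null(recording$clinical)) {
    off <- adjust_updrs(recording$clinical$updrs_off_raw,
                        recording$clinical$scale_version)
    on <- adjust_updrs(recording$clinical$updrs_on_raw,
                       recording$clinical$scale_version)
    res$abs_delta_updrs <- off - on
    res$pct_delta_updrs <- if (off > 0) (off - on) / off * 100 else NA_real_
  }
  if (!is.na(res$abs_delta_updrs)) {
    res$classification <- classify_lr(res$abs_delta_updrs, zone)
    res$flag_uncertain <- res$classification == "uncertain"
  }

  if (is.null(dt_est)) {
    res$reason <- "DT unavailable"
    return(structure(res, class = c("ldct_result", class(res))))
  }
  if (is.null(et_est)) {
    res$reason <- "ET unavailable"
    res$mfsl_dt <- dt_est$mean
    return(structure(res, class = c("ldct_result", class(res))))
  }
  res$mfsl_dt <- dt_est$mean
  res$mfsl_et <- et_est$mean
  lr <- compute_lr(dt_est$mean, et_est$mean)
  res$abs_delta_pkg <- lr$abs_delta_pkg
  res$pct_delta_pkg <- lr$pct_delta_pkg

  # The exclusion heuristics target patients; controls (nominal dose, no
  # pharmacological response) are never flagged and always retained.
  if (recording$group == "control") {
    res$flag_already_on <- FALSE
    res$flag_variable_amplitude <- FALSE
    res$flag_variable_latency <- FALSE
    return(structure(res, class = c("ldct_result", class(res))))
  }

  # daytime pool for the already-ON rule: from `search_start` past the
  # first dose of each day until 18:00, usable epochs only
  epochs <- recording$epochs
  day_of <- floor(dw$align_times / 1440)
  day_idx <- unlist(lapply(seq_along(dw$align_times), function(d) {
    from <- dw$align_times[d] + search_start
    to <- day_of[d] * 1440 + daytime_end_minute
    which(epochs$timestamp_min >= from & epochs$timestamp_min <= to &
            labels == "active")
  }), use.names = FALSE)
  daytime_est <- if (length(day_idx)) {
    estimate_mfsl_at(model, feat_at(day_idx))
  }
  res$flag_already_on <- flag_already_on(daytime_est, res$mfsl_dt)

  lats <- per_day_trough_latency(recording, dw$align_times, labels,
                                 search_start, search_end)
  vflags <- flag_variability(dt_est, et_est, lats)
  res$flag_variable_amplitude <- vflags$variable_amplitude
  res$flag_variable_latency <- vflags$variable_latency
  structure(res, class = c("ldct_result", class(res)))
}

#' Run the instrumented challenge over a cohort
#'
#' @param recordings list of `pkg_recording`.
#' @param model a trained `severity_model`.
#' @param ... passed to [run_ldct()].
#' @return data frame with one `ldct_result` row per subject.
#' @export
run_ldct_cohort <- function(recordings, model, ...) {
  out <- do.call(rbind, lapply(recordings, function(r) {
    as.data.frame(run_ldct(r, model, ...))
  }))
  rownames(out) <- NULL
  out
}
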