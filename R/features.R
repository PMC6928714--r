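# Engineered per-epoch features: moving and weighted moving percentiles of
# the bradykinesia score (BKS), tremor transforms, and the dose-aligned
# smoothed weekly BKS series.

#' Moving percentile over a centered epoch window
#'
#' The value at epoch i is the nearest-rank q-th percentile of the usable
#' values inside the centered window. Windows shrink at the series edges
#' and around excluded (unusable) epochs; an epoch whose window holds no
#' usable value yields `NA`.
#'
#' @param series numeric vector on the epoch grid.
#' @param window_epochs odd window length (default 15 epochs = 30 min).
#' @param q percentile in (0, 100).
#' @param usable logical mask of epochs allowed to contribute (default:
#'   all non-NA epochs).
#' @param at integer indices at which to evaluate (default: every epoch).
#' @return numeric vector of length `length(at)`.
#' @export
moving_percentile <- function(series, window_epochs = 15, q,
                              usable = NULL, at = NULL) {
  check_window_args(window_epochs, q)
  usable <- usable %||% !is.na(series)
  at <- at %||% seq_along(series)
  h <- (window_epochs - 1L) %/% 2L
  n <- length(series)
  vapply(at, function(i) {
    j <- max(1L, i - h):min(n, i + h)
    vals <- series[j][usable[j]]
    if (!length(vals)) NA_real_ else nearest_rank_percentile(vals, q)
  }, numeric(1))
}

#' Weighted moving percentile with a triangular kernel
#'
#' As [moving_percentile()], but each epoch in the window carries a
#' linear weight, maximal at the window center and declining linearly and
#' symmetrically towards the edges. The weighted q-th percentile is the
#' smallest value whose cumulative normalized weight (values sorted
#' ascending) reaches q/100; with uniform weights this reduces exactly to
#' the unweighted nearest-rank percentile.
#'
#' @inheritParams moving_percentile
#' @param weights optional kernel of length `window_epochs` replacing the
#'   triangular default.
#' @return numeric vector of length `length(at)`; `NA` where the total
#'   usable weight in the window is zero.
#' @export
weighted_moving_percentile <- function(series, window_epochs = 15, q,
                                       usable = NULL, at = NULL,
                                       weights = NULL) {
  check_window_args(window_epochs, q)
  usable <- usable %||% !is.na(series)
  at <- at %||% seq_along(series)
  h <- (window_epochs - 1L) %/% 2L
  kern <- weights %||% triangular_weights(window_epochs)
  if (length(kern) != window_epochs) {
    stopf("weights must have length %d", window_epochs)
  }
  n <- length(series)
  vapply(at, function(i) {
    j <- max(1L, i - h):min(n, i + h)
    keep <- usable[j]
    if (!any(keep)) return(NA_real_)
    w <- kern[j - i + h + 1L][keep]
    weighted_percentile(series[j][keep], w, q)
  }, numeric(1))
}

check_window_args <- function(window_epochs, q) {
  if (window_epochs %% 2 == 0) {
    stopf("window_epochs must be odd, got %d", window_epochs)
  }
  if (q <= 0 || q >= 100) stopf("q must be in (0, 100), got %s", q)
}

#' Log tremor transform
#'
#' BKS scales logarithmically with movement acceleration while the tremor
#' amplitude is on the raw acceleration-derived scale; `log10(1 + ta)`
#' brings tremor onto a comparable scaling and maps "no tremor" (0) to 0.
#'
#' @param ta tremor amplitude, >= 0.
#' @return `log10(1 + ta)`.
#' @export
log_tremor <- function(ta) {
  if (any(ta < 0, na.rm = TRUE)) stopf("tremor amplitude must be >= 0")
  log10(1 + ta)
}

#' Dose-aligned smoothed weekly BKS series
#'
#' Each recorded day is aligned on the acknowledgement of its first dose
#' (or on a supplied nominal alignment time); for every 2-minute offset
#' the across-day median of the usable BKS values is taken, then smoothed
#' with a centered moving average. The resulting series summarizes the
#' typical post-dose response over the whole recording and is what the
#' effect-time search operates on.
#'
#' @param recording a `pkg_recording`.
#' @param align_times minutes-since-start alignment anchors, one per day
#'   to use; default: acknowledgements of first-of-day dose events.
#' @param labels activity labels from [label_activity()] (computed if
#'   omitted); only active epochs contribute.
#' @param offsets offsets (minutes, 2-min grid) to evaluate, relative to
#'   the start of the epoch containing the alignment time.
#' @param smooth_window centered moving-average length in offsets
#'   (default 5); use 1 for no smoothing.
#' @return data frame with `offset_min`, `value` (smoothed BKS, `NA`
#'   where no day contributes) and `n_days` contributing at each offset.
#' @export
smoothed_weekly_series <- function(recording, align_times = NULL,
                                   labels = NULL,
                                   offsets = seq(-60, 360, by = 2),
                                   smooth_window = 5) {
  labels <- labels %||% label_activity(recording)
  if (is.null(align_times)) {
    de <- recording$dose_events
    if (is.null(de) || !any(de$first_of_day &
                            !is.na(de$acknowledgement_min))) {
      stopf("recording %s has no acknowledged first-of-day dose to align on",
            recording$subject_id)
    }
    align_times <- de$acknowledgement_min[de$first_of_day &
                                          !is.na(de$acknowledgement_min)]
  }
  epochs <- recording$epochs
  t0 <- epochs$timestamp_min[1L]
  step <- EPOCH_MINUTES
  usable <- labels == "active"
  # per-day aligned values: rows = days, cols = offsets
  anchor <- floor((align_times - t0) / step) * step + t0
  mat <- vapply(anchor, function(a0) {
    tt <- a0 + offsets
    idx <- match(tt, epochs$timestamp_min)
    val <- epochs$bks[idx]
    val[is.na(idx) | !usable[replace(idx, is.na(idx), 1L)]] <- NA_real_
    val
  }, numeric(length(offsets)))
  mat <- matrix(mat, nrow = length(offsets))
  raw <- apply(mat, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  n_days <- rowSums(!is.na(mat))
  sm <- raw
  if (smooth_window > 1) {
    hh <- (smooth_window - 1L) %/% 2L
    m <- length(raw)
    sm <- vapply(seq_len(m), function(i) {
      v <- raw[max(1L, i - hh):min(m, i + hh)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    sm[is.na(raw)] <- NA_real_
  }
  data.frame(offset_min = offsets, value = sm, n_days = n_days)
}

#' Names of the features entering the severity classifiers
#'
#' The default model consumes the 30-minute moving 10th and 25th BKS
#' percentiles together with the log weighted moving median of tremor
#' amplitude; the remaining candidates carry largely redundant
#' information.
#'
#' @return character vector of feature names.
#' @export
selected_features <- function() c("BKS_M10P", "BKS_M25P", "TA_WM50P_Log")

#' Names of all candidate features
#' @return character vector.
#' @export
candidate_features <- function() {
  c("BK", paste0("BKS_M", c(10, 25, 50, 75, 90), "P"),
    paste0("BKS_WM", c(10, 25, 50, 75, 90), "P"),
    "TA", "TA_M50P", "TA_WM50P", "TA_WM50P_Log")
}

#' Compute the candidate feature table for a recording
#'
#' Moving and triangular-weighted moving percentiles of BKS (10th, 25th,
#' 50th, 75th, 90th), the moving and weighted moving median of tremor
#' amplitude, and its log transform, all over a 30-minute centered window
#' of active on-wrist epochs.
#'
#' @param recording a `pkg_recording`.
#' @param at epoch indices to evaluate (default: every epoch). Restricting
#'   to the epochs actually needed (dose/effect windows, daytime spans)
#'   keeps multi-day cohorts fast.
#' @param labels activity labels (computed if omitted).
#' @param features `"all"` or `"selected"` (just the model's feature set).
#' @param window_epochs odd window length, default 15.
#' @return data frame with `timestamp_min`, `usable` (whether the epoch
#'   itself is active) and one column per feature.
#' @export
featurize <- function(recording, at = NULL, labels = NULL,
                      features = c("all", "selected"), window_epochs = 15) {
  features <- match.arg(features)
  labels <- labels %||% label_activity(recording, window_epochs)
  epochs <- recording$epochs
  at <- at %||% seq_len(nrow(epochs))
  usable <- labels == "active"
  bks <- epochs$bks
  ta <- epochs$tremor_amplitude
  out <- data.frame(timestamp_min = epochs$timestamp_min[at],
                    usable = usable[at])
  mp <- function(x, q) moving_percentile(x, window_epochs, q, usable, at)
  wmp <- function(x, q) {
    weighted_moving_percentile(x, window_epochs, q, usable, at)
  }
  if (features == "all") {
    out$BK <- ifelse(usable[at], bks[at], NA_real_)
    for (q in c(10, 25, 50, 75, 90)) out[[paste0("BKS_M", q, "P")]] <- mp(bks, q)
    for (q in c(10, 25, 50, 75, 90)) out[[paste0("BKS_WM", q, "P")]] <- wmp(bks, q)
    out$TA <- ifelse(usable[at], ta[at], NA_real_)
    out$TA_M50P <- mp(ta, 50)
    out$TA_WM50P <- wmp(ta, 50)
    out$TA_WM50P_Log <- log_tremor(out$TA_WM50P)
  } else {
    out$BKS_M10P <- mp(bks, 10)
    out$BKS_M25P <- mp(bks, 25)
    out$TA_WM50P_Log <- log_tremor(wmp(ta, 50))
  }
  attr(out, "selected") <- selected_features()
  out
}
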