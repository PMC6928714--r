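# Synthetic cohort generator.
#
# Emulates multi-day wrist-sensor recordings with known ground truth so
# every downstream stage (activity labeling, features, dose windows,
# severity model, levodopa-response estimation, evaluation) is testable
# without access to clinical recordings. One recording per subject at a
# 2-minute epoch cadence: nightly sleep and daytime inactivity bouts with
# high BKS, off-wrist gaps, severity-linked BKS via an affine
# UPDRS III -> BKS link, a single first-of-day levodopa dose whose effect
# troughs at a per-day latency drawn from a truncated normal, day-to-day
# amplitude variability, tremor with severity-linked prevalence, control
# subjects with a low flat BKS, and "already ON" subjects whose morning
# severity understates their worst daytime severity.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the package models: 6-day
#' recordings at 2-minute resolution, first dose reminders at 07:00 with
#' wake at 06:30 and sleep from 23:00, a levodopa effect trough at
#' 62 +/- 10 min (truncated to the 46-90 min search support), OFF-state
#' UPDRS III drawn around 48 +/- 13 with an OFF-to-ON improvement around
#' 22 +/- 11, 19% of patients "already ON" in the morning, and an affine
#' UPDRS -> BKS link (BKS is linearly correlated with UPDRS III) with
#' slope 0.45 BKS per UPDRS point plus Gaussian epoch noise.
#'
#' @param n_pwp,n_controls subject counts (>= 0).
#' @param n_days recording length in days (>= 1, default 6).
#' @param epoch_minutes epoch cadence (default 2).
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical cohorts.
#' @param bks_link_slope,bks_link_intercept affine UPDRS III -> BKS link.
#' @param noise_sd per-epoch Gaussian BKS noise, BKS units.
#' @param inactivity_rate stationary fraction of awake epochs spent in
#'   daytime inactivity bouts (in \[0, 1\]).
#' @param offwrist_rate stationary fraction of epochs off wrist.
#' @param frac_already_on fraction of patients simulated as already ON.
#' @param latency_mean,latency_sd,latency_support per-day minutes from
#'   dose acknowledgement to peak effect (truncated normal).
#' @param response_amplitude_cv day-to-day coefficient of variation of the
#'   response amplitude.
#' @param wake_minute,sleep_minute,reminder_minute,control_dt_minute clock
#'   minutes (from midnight) of waking, sleep onset, the patients' first
#'   dose reminder, and the controls' nominal dose time.
#' @param sleep_bks_mean,sleep_bks_sd BKS level during sleep/inactivity
#'   bouts (well above the 40-unit inactivity threshold).
#' @param inactive_bout_mean,offwrist_bout_mean mean bout lengths, epochs.
#' @param onset_delay_min,wearoff_min minutes from acknowledgement to the
#'   start of the effect decline, and from trough back to the OFF level.
#' @param updrs_off_mean,updrs_off_sd,delta_mean,delta_sd OFF-state
#'   UPDRS III and OFF-to-ON improvement distributions (adjusted scale).
#' @param older_scale_fraction fraction of patients whose clinical labels
#'   are recorded on the older UPDRS scale (raw total 7 points lower).
#' @param tremor_base_rate,tremor_sev_slope,tremor_amp_scale tremor
#'   prevalence (per awake epoch, increasing with current severity) and
#'   amplitude scale.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_pwp, n_controls, n_days = 6,
                              epoch_minutes = 2, seed = 1,
                              bks_link_slope = 0.45, bks_link_intercept = 2,
                              noise_sd = 6, inactivity_rate = 0.08,
                              offwrist_rate = 0.02, frac_already_on = 0.19,
                              latency_mean = 62, latency_sd = 10,
                              latency_support = c(46, 90),
                              response_amplitude_cv = 0.15,
                              wake_minute = 390, sleep_minute = 1380,
                              reminder_minute = 420, control_dt_minute = 600,
                              sleep_bks_mean = 55, sleep_bks_sd = 4,
                              inactive_bout_mean = 15, offwrist_bout_mean = 10,
                              onset_delay_min = 10, wearoff_min = 120,
                              updrs_off_mean = 48, updrs_off_sd = 13,
                              delta_mean = 22, delta_sd = 11,
                              older_scale_fraction = 2 / 3,
                              tremor_base_rate = 0.10,
                              tremor_sev_slope = 0.005,
                              tremor_amp_scale = 1) {
  cfg <- as.list(environment())
  rates <- c(inactivity_rate = inactivity_rate, offwrist_rate = offwrist_rate,
             frac_already_on = frac_already_on,
             older_scale_fraction = older_scale_fraction)
  if (any(rates < 0 | rates > 1)) {
    bad <- names(rates)[which(rates < 0 | rates > 1)[1L]]
    stopf("configuration error: %s must be in [0, 1]", bad)
  }
  if (n_pwp < 0 || n_controls < 0 || n_pwp + n_controls == 0) {
    stopf("configuration error: need non-negative counts and >= 1 subject")
  }
  if (n_days < 1) stopf("configuration error: n_days must be >= 1")
  if (epoch_minutes <= 0) stopf("configuration error: epoch_minutes must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a cohort of recordings with ground truth
#'
#' @param config a [simulation_config()].
#' @return list with `recordings` (list of `pkg_recording`) and `truth`
#'   (one row per subject: group, adjusted-scale `updrs_off`/`updrs_on`,
#'   disease duration, response latency parameters, amplitude CV,
#'   `already_on`, first dose size). Controls have zero UPDRS and no dose
#'   events. Each recording additionally carries epoch-level truth
#'   (instantaneous severity, inactivity-bout membership) and per-day dose
#'   truth (latency, ON-level severity) in its `truth` element.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_pwp <- config$n_pwp
  n_controls <- config$n_controls
  truth <- sim_subject_truth(config)
  recordings <- lapply(seq_len(nrow(truth)), function(i) {
    simulate_recording(truth[i, ], config)
  })
  list(recordings = recordings, truth = truth)
}

# Subject-level ground truth. Patients are assigned an OFF-state severity
# level by cycling through levels 3,4,2,5,1 (moderate/severe enriched, as
# in referral cohorts) with the UPDRS III drawn uniformly inside the
# level's interval; the OFF-to-ON improvement is truncated normal.
sim_subject_truth <- function(config) {
  n_pwp <- config$n_pwp
  n_controls <- config$n_controls
  lev_cycle <- c(3, 4, 2, 5, 1)
  level_lo <- c(12, 24, 36, 48.5, 60.5)
  level_hi <- c(21.5, 34, 46.5, 59, 80)
  rows <- list()
  if (n_pwp > 0) {
    lev <- rep_len(lev_cycle, n_pwp)
    off <- stats::runif(n_pwp, level_lo[lev], level_hi[lev])
    delta <- rtruncnorm(n_pwp, config$delta_mean, config$delta_sd,
                        lower = 4, upper = Inf)
    on <- pmax(off - delta, 2)
    # "already ON" requires a treated-range morning (ON level below the
    # gate) and enough OFF-ON contrast for the afternoon deterioration to
    # be visible (>= 16 points, about 1.3 severity levels)
    eligible <- which(on < 30 & off - on >= 16)
    n_on <- min(round(config$frac_already_on * n_pwp), length(eligible))
    already <- rep(FALSE, n_pwp)
    if (n_on > 0) already[sample(eligible, n_on)] <- TRUE
    older <- stats::runif(n_pwp) < config$older_scale_fraction
    # older-scale raw totals are the adjusted score minus 7, so adjusted
    # scores of older-scale subjects cannot sit below 7
    on[older] <- pmax(on[older], 7)
    rows$pwp <- data.frame(
      subject_id = sprintf("pwp%03d", seq_len(n_pwp)),
      group = "PwP", updrs_off = off, updrs_on = on,
      disease_duration = round(rtruncnorm(n_pwp, 10, 5, 1, 25), 1),
      response_latency_mean = config$latency_mean,
      # day-to-day latency spread differs between subjects (stable versus
      # erratic gastric emptying); the multiplier is scaled so the pooled
      # across-dose SD still matches the configured latency_sd
      response_latency_sd = config$latency_sd *
        stats::runif(n_pwp, 0.4, 1.5),
      response_amplitude_cv = config$response_amplitude_cv,
      already_on = already,
      first_dose_mg = 50 * round(rtruncnorm(n_pwp, 164, 79, 50, 450) / 50),
      scale_version = ifelse(older, "UPDRS", "MDS-UPDRS"))
  }
  if (n_controls > 0) {
    rows$ctl <- data.frame(
      subject_id = sprintf("ctl%03d", seq_len(n_controls)),
      group = "control", updrs_off = 0, updrs_on = 0,
      disease_duration = 0, response_latency_mean = NA_real_,
      response_latency_sd = NA_real_, response_amplitude_cv = NA_real_,
      already_on = FALSE, first_dose_mg = NA_real_,
      scale_version = "MDS-UPDRS")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Instantaneous awake severity (UPDRS III units) for one subject as a
# piecewise-linear function of absolute minutes.
sim_severity_breakpoints <- function(subj, config, dose_truth) {
  n_days <- config$n_days
  day0 <- (seq_len(n_days) - 1) * 1440
  if (subj$group == "control") {
    return(list(x = c(0, n_days * 1440), y = c(0, 0)))
  }
  off <- subj$updrs_off
  if (subj$already_on) {
    on <- subj$updrs_on
    x <- as.vector(rbind(day0, day0 + 720, day0 + 840, day0 + 1439))
    y <- rep(c(on, on, off, off), n_days)
    dim(x) <- NULL
    return(list(x = x, y = y))
  }
  xs <- ys <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    ack <- dose_truth$acknowledgement_min[d]
    lat <- dose_truth$latency_min[d]
    on_d <- dose_truth$on_severity[d]
    xs[[d]] <- c(day0[d], ack + config$onset_delay_min, ack + lat,
                 ack + lat + config$wearoff_min, day0[d] + 1439)
    ys[[d]] <- c(off, off, on_d, off, off)
  }
  x <- unlist(xs)
  y <- unlist(ys)
  keep <- !duplicated(x)
  list(x = x[keep], y = y[keep])
}

simulate_recording <- function(subj, config) {
  step <- config$epoch_minutes
  n <- config$n_days * (1440 %/% step)
  t <- (seq_len(n) - 1) * step
  tod <- t %% 1440
  asleep <- tod >= config$sleep_minute | tod < config$wake_minute
  day0 <- (seq_len(config$n_days) - 1) * 1440

  dose_truth <- NULL
  dose_events <- NULL
  if (subj$group == "PwP") {
    delay <- sample(c(0, 2, 4), config$n_days, replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
    rem <- day0 + config$reminder_minute
    ack <- rem + delay
    lat <- rtruncnorm(config$n_days, subj$response_latency_mean,
                      subj$response_latency_sd,
                      config$latency_support[1], config$latency_support[2])
    amp <- pmin(pmax(1 + config$response_amplitude_cv *
                       stats::rnorm(config$n_days), 0.3), 1.7)
    on_sev <- pmax(subj$updrs_off - amp * (subj$updrs_off - subj$updrs_on), 0)
    dose_truth <- data.frame(day = seq_len(config$n_days),
                             reminder_min = rem, acknowledgement_min = ack,
                             latency_min = lat, on_severity = on_sev)
    dose_events <- data.frame(reminder_min = rem, acknowledgement_min = ack,
                              first_of_day = TRUE)
  }
  bp <- sim_severity_breakpoints(subj, config, dose_truth)
  sev <- stats::approx(bp$x, bp$y, xout = t, rule = 2)$y

  bks <- config$bks_link_intercept + config$bks_link_slope * sev +
    stats::rnorm(n, 0, config$noise_sd)
  # daytime inactivity bouts among awake epochs
  awake_idx <- which(!asleep)
  inactive <- logical(n)
  inactive[awake_idx] <- markov_bouts(length(awake_idx),
                                      config$inactivity_rate,
                                      config$inactive_bout_mean)
  resting <- asleep | inactive
  bks[resting] <- stats::rnorm(sum(resting), config$sleep_bks_mean,
                               config$sleep_bks_sd)
  bks <- pmin(pmax(bks, 0), 160)

  off_wrist <- markov_bouts(n, config$offwrist_rate, config$offwrist_bout_mean)

  p_trem <- ifelse(asleep, 0.01,
                   pmin(config$tremor_base_rate +
                          config$tremor_sev_slope * sev, 0.6))
  has_trem <- stats::runif(n) < p_trem
  ta <- numeric(n)
  ta[has_trem] <- stats::rlnorm(sum(has_trem),
                                log(config$tremor_amp_scale *
                                      (0.5 + 0.03 * sev[has_trem] + 1e-6)),
                                0.6)

  clinical <- NULL
  if (subj$group == "PwP") {
    shift <- if (subj$scale_version == "UPDRS") 7 else 0
    clinical <- list(updrs_off_raw = subj$updrs_off - shift,
                     updrs_on_raw = subj$updrs_on - shift,
                     scale_version = subj$scale_version,
                     disease_duration_years = subj$disease_duration,
                     first_dose_led_mg = subj$first_dose_mg)
  }
  epochs <- data.frame(timestamp_min = t, bks = bks, tremor_amplitude = ta,
                       off_wrist = off_wrist)
  new_recording(subj$subject_id, subj$group, epochs, dose_events, clinical,
                truth = list(severity = sev, inactive_bout = inactive,
                             asleep = asleep, doses = dose_truth))
}

#' Simulate a single control recording
#'
#' A control recording carries no dose events; its nominal dose-time clock
#' minute (`control_dt_minute`, default 10:00) always falls on a valid
#' epoch of the 2-minute grid.
#'
#' @param config a [simulation_config()] (its `n_controls`/`n_pwp` counts
#'   are ignored; one control is produced).
#' @return a `pkg_recording` for one control subject.
#' @export
simulate_controls_day <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  subj <- data.frame(subject_id = "ctl001", group = "control",
                     updrs_off = 0, updrs_on = 0, disease_duration = 0,
                     response_latency_mean = NA_real_,
                     response_latency_sd = NA_real_,
                     response_amplitude_cv = NA_real_, already_on = FALSE,
                     first_dose_mg = NA_real_, scale_version = "MDS-UPDRS")
  simulate_recording(subj, config)
}
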