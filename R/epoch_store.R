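# Data model and I/O for epoch streams, dose events and clinical labels.
#
# A "recording" is the package's container for one subject's multi-day
# wrist-sensor stream: a data frame of 2-minute epochs (bradykinesia score
# BKS, tremor amplitude, off-wrist flag), the first-of-day dose events
# (reminder and acknowledgement times), and optional clinical labels
# (UPDRS III OFF/ON totals).

EPOCH_MINUTES <- 2

#' Construct a recording
#'
#' @param subject_id character scalar.
#' @param group `"PwP"` (person with Parkinson's) or `"control"`.
#' @param epochs data frame with columns `timestamp_min` (minutes since
#'   recording start, strictly increasing on the 2-minute grid), `bks`,
#'   `tremor_amplitude` (>= 0; 0 means no tremor) and `off_wrist`
#'   (logical; off-wrist epochs are unavailable for analysis).
#' @param dose_events optional data frame with columns `reminder_min`,
#'   `acknowledgement_min` and `first_of_day`; at most one first-of-day
#'   dose per calendar day (1440-minute blocks), and acknowledgements
#'   never precede their reminders.
#' @param clinical optional list with elements `updrs_off_raw`,
#'   `updrs_on_raw`, `scale_version` (`"UPDRS"` or `"MDS-UPDRS"`),
#'   `disease_duration_years`, `first_dose_led_mg`.
#' @param truth optional generator ground truth (kept out of all analyses;
#'   see [simulate_cohort()]).
#' @return an object of class `pkg_recording`.
#' @export
new_recording <- function(subject_id, group, epochs, dose_events = NULL,
                          clinical = NULL, truth = NULL) {
  if (!group %in% c("PwP", "control")) {
    stopf("unknown group label '%s' for subject %s", group, subject_id)
  }
  required <- c("timestamp_min", "bks", "tremor_amplitude", "off_wrist")
  missing_cols <- setdiff(required, names(epochs))
  if (length(missing_cols)) {
    stopf("epoch table for subject %s is missing column(s): %s",
          subject_id, paste(missing_cols, collapse = ", "))
  }
  bad <- which(epochs$tremor_amplitude < 0)
  if (length(bad)) {
    stopf("tremor_amplitude < 0 at row %d (subject %s)", bad[1L], subject_id)
  }
  if (any(diff(epochs$timestamp_min) <= 0)) {
    stopf("timestamps not strictly increasing (subject %s)", subject_id)
  }
  if (!is.null(dose_events) && nrow(dose_events)) {
    both <- !is.na(dose_events$reminder_min) &
      !is.na(dose_events$acknowledgement_min)
    if (any(dose_events$acknowledgement_min[both] <
            dose_events$reminder_min[both])) {
      stopf("acknowledgement before reminder (subject %s)", subject_id)
    }
    fod <- dose_events[dose_events$first_of_day, , drop = FALSE]
    if (anyDuplicated(floor(fod$reminder_min / 1440))) {
      stopf("more than one first-of-day dose in a calendar day (subject %s)",
            subject_id)
    }
  }
  structure(
    list(subject_id = subject_id, group = group, epochs = epochs,
         dose_events = dose_events, clinical = clinical, truth = truth),
    class = "pkg_recording")
}

#' @export
print.pkg_recording <- function(x, ...) {
  cat(sprintf("<pkg_recording> subject %s (%s): %d epochs, %d dose events\n",
              x$subject_id, x$group, nrow(x$epochs),
              if (is.null(x$dose_events)) 0L else nrow(x$dose_events)))
  invisible(x)
}

#' Write a cohort of recordings to plain-text files
#'
#' Epochs go to one CSV (columns `subject_id`, `group`, `timestamp_min`,
#' `bks`, `tremor_amplitude`, `off_wrist` as 0/1), dose events to a JSON
#' file keyed by subject, and clinical labels to a CSV.
#'
#' @param recordings list of `pkg_recording` objects.
#' @param epoch_csv,dose_json,clinical_csv output paths (`dose_json` and
#'   `clinical_csv` optional).
#' @return invisibly, the epoch CSV path.
#' @export
write_epochs <- function(recordings, epoch_csv, dose_json = NULL,
                         clinical_csv = NULL) {
  tabs <- lapply(recordings, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group,
               timestamp_min = r$epochs$timestamp_min,
               bks = r$epochs$bks,
               tremor_amplitude = r$epochs$tremor_amplitude,
               off_wrist = as.integer(r$epochs$off_wrist))
  })
  utils::write.csv(do.call(rbind, tabs), epoch_csv, row.names = FALSE)
  if (!is.null(dose_json)) {
    doses <- lapply(recordings, function(r) {
      if (is.null(r$dose_events) || !nrow(r$dose_events)) return(list())
      lapply(seq_len(nrow(r$dose_events)), function(i) {
        d <- r$dose_events[i, ]
        list(reminder_min = d$reminder_min,
             acknowledgement_min = d$acknowledgement_min,
             first_of_day = d$first_of_day)
      })
    })
    names(doses) <- vapply(recordings, `[[`, "", "subject_id")
    jsonlite::write_json(doses, dose_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(clinical_csv)) {
    rows <- lapply(recordings, function(r) {
      if (is.null(r$clinical)) return(NULL)
      data.frame(subject_id = r$subject_id,
                 updrs_off_raw = r$clinical$updrs_off_raw,
                 updrs_on_raw = r$clinical$updrs_on_raw,
                 scale_version = r$clinical$scale_version,
                 disease_duration_years = r$clinical$disease_duration_years,
                 first_dose_led_mg = r$clinical$first_dose_led_mg)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) {
      utils::write.csv(do.call(rbind, rows), clinical_csv, row.names = FALSE)
    }
  }
  invisible(epoch_csv)
}

#' Read a cohort of recordings
#'
#' Inverse of [write_epochs()]: a round-trip write/read is structurally
#' the identity. Malformed rows are rejected with their row number.
#'
#' @param epoch_csv path to the epoch CSV.
#' @param dose_json,clinical_csv optional companion files.
#' @return list of `pkg_recording` objects, ordered as in the CSV.
#' @export
read_epochs <- function(epoch_csv, dose_json = NULL, clinical_csv = NULL) {
  tab <- utils::read.csv(epoch_csv, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "timestamp_min", "bks",
                "tremor_amplitude", "off_wrist")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stopf("epoch file %s is missing column(s): %s", epoch_csv,
          paste(missing_cols, collapse = ", "))
  }
  bad <- which(tab$tremor_amplitude < 0)
  if (length(bad)) {
    stopf("tremor_amplitude < 0 at row %d of %s", bad[1L], epoch_csv)
  }
  doses <- if (!is.null(dose_json)) {
    jsonlite::read_json(dose_json, simplifyVector = FALSE)
  }
  clin <- if (!is.null(clinical_csv) && file.exists(clinical_csv)) {
    utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  }
  ids <- unique(tab$subject_id)
  lapply(ids, function(id) {
    sub <- tab[tab$subject_id == id, , drop = FALSE]
    epochs <- data.frame(timestamp_min = sub$timestamp_min, bks = sub$bks,
                         tremor_amplitude = sub$tremor_amplitude,
                         off_wrist = sub$off_wrist != 0)
    de <- NULL
    if (!is.null(doses) && !is.null(doses[[id]]) && length(doses[[id]])) {
      de <- do.call(rbind, lapply(doses[[id]], function(d) {
        data.frame(reminder_min = d$reminder_min,
                   acknowledgement_min = d$acknowledgement_min,
                   first_of_day = isTRUE(d$first_of_day))
      }))
    }
    cl <- NULL
    if (!is.null(clin) && id %in% clin$subject_id) {
      row <- clin[clin$subject_id == id, ][1L, ]
      cl <- list(updrs_off_raw = row$updrs_off_raw,
                 updrs_on_raw = row$updrs_on_raw,
                 scale_version = row$scale_version,
                 disease_duration_years = row$disease_duration_years,
                 first_dose_led_mg = row$first_dose_led_mg)
    }
    new_recording(id, sub$group[1L], epochs, de, cl)
  })
}

#' Label epochs as active, inactive or off-wrist
#'
#' Off-wrist epochs are unavailable for analysis regardless of BKS. Among
#' the remaining epochs, an epoch is inactive when the linearly weighted
#' moving median of BKS in the centered window exceeds the threshold
#' (sustained high BKS indicates sleep or inactivity rather than
#' bradykinetic movement); all other epochs are active.
#'
#' @param recording a `pkg_recording`.
#' @param window_epochs odd window length in epochs (default 15, i.e. 30
#'   minutes at the 2-minute cadence).
#' @param inactive_threshold BKS threshold (default 40).
#' @return character vector, one of `"active"`, `"inactive"`,
#'   `"off_wrist"` per epoch.
#' @export
label_activity <- function(recording, window_epochs = 15,
                           inactive_threshold = 40) {
  if (window_epochs %% 2 == 0) {
    stopf("window_epochs must be odd, got %d", window_epochs)
  }
  epochs <- recording$epochs
  onwrist <- !epochs$off_wrist
  wmm <- weighted_moving_percentile(epochs$bks, window_epochs, 50,
                                    usable = onwrist)
  labels <- rep("active", nrow(epochs))
  labels[!is.na(wmm) & wmm > inactive_threshold] <- "inactive"
  labels[is.na(wmm) & onwrist] <- "active"
  labels[!onwrist] <- "off_wrist"
  labels
}
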