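# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# A small default-condition cohort for module-level checks.
small_cohort <- function() {
  cached("small", function() {
    cfg <- simulation_config(n_pwp = 20, n_controls = 15, n_days = 6,
                             seed = 7)
    simulate_cohort(cfg)
  })
}

# The evaluation cohort: 150 patients + 150 controls under the default
# generator conditions (the affine severity link with 6-BKS epoch noise),
# with the severity model trained on it and the per-subject challenge
# results computed. Built lazily because it takes a few minutes.
evaluation_fixture <- function() {
  cached("evaluation", function() {
    cfg <- simulation_config(n_pwp = 150, n_controls = 150, n_days = 6,
                             seed = 424242)
    cohort <- simulate_cohort(cfg)
    samples <- build_training_samples(cohort$recordings)
    model <- train_severity_model(samples, seed = 424242)
    results <- run_ldct_cohort(cohort$recordings, model)
    list(config = cfg, cohort = cohort, samples = samples, model = model,
         results = results)
  })
}

# A hand-built recording on the 2-minute grid: one day, constant or
# supplied BKS, optional dose acknowledgement, no off-wrist epochs.
make_flat_recording <- function(bks = 10, n_epochs = 720, subject_id = "s1",
                                group = "PwP", ack_min = NULL,
                                tremor = 0, off_wrist = NULL) {
  t <- (seq_len(n_epochs) - 1) * 2
  epochs <- data.frame(timestamp_min = t,
                       bks = rep_len(bks, n_epochs),
                       tremor_amplitude = rep_len(tremor, n_epochs),
                       off_wrist = if (is.null(off_wrist))
                         rep(FALSE, n_epochs) else off_wrist)
  de <- NULL
  if (!is.null(ack_min)) {
    de <- data.frame(reminder_min = ack_min - 2,
                     acknowledgement_min = ack_min, first_of_day = TRUE)
  }
  new_recording(subject_id, group, epochs, de)
}

# A degenerate severity model whose five classifiers vote by fixed
# intercept sign, for exercising the vote-sum prediction rule.
make_vote_model <- function(intercepts) {
  feats <- selected_features()
  classifiers <- lapply(intercepts, function(b0) {
    list(kind = "glmnet", threshold = NA_real_, intercept = b0,
         coef = rep(0, length(feats)),
         center = stats::setNames(rep(0, length(feats)), feats),
         scale = stats::setNames(rep(1, length(feats)), feats),
         rotation = NULL)
  })
  structure(list(binning = mfsl_binning(), model_family = "logistic",
                 features = feats, classifiers = classifiers,
                 test_subjects = NULL, training_report = NULL),
            class = "severity_model")
}
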