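test_that("older-scale UPDRS totals gain 7 points, MDS totals pass through", {
  expect_identical(adjust_updrs(41, "UPDRS"), 48)
  expect_identical(adjust_updrs(0, "UPDRS"), 7)
  expect_identical(adjust_updrs(48, "MDS-UPDRS"), 48)
  expect_error(adjust_updrs(10, "UPDRS-IV"), "unknown scale")
  expect_error(adjust_updrs(-1, "UPDRS"), ">= 0")
})

test_that("severity binning maps scores to the six ordinal levels", {
  expect_identical(updrs_to_mfsl(35), 3L)
  expect_identical(updrs_to_mfsl(60), 5L)
  expect_identical(updrs_to_mfsl(9.9), 0L)
  expect_identical(updrs_to_mfsl(c(0, 10, 22.5, 34.9, 47.5, 59.9, 100)),
                   c(0L, 1L, 2L, 2L, 4L, 4L, 5L))
  expect_error(updrs_to_mfsl(-5), ">= 0")
})

test_that("the ordinal decomposition yields the five expected thresholds", {
  thr <- ordinal_thresholds(mfsl_binning())
  expect_length(thr, 5)
  expect_identical(thr[3], 35)
  expect_identical(thr, c(10, 22.5, 35, 47.5, 60))
  expect_identical(ordinal_thresholds(mfsl_binning(10, 10)),
                   c(10, 20, 30, 40, 50))
  expect_identical(length(thr), as.integer(mfsl_binning()$n_levels) - 1L)
})

test_that("training samples from a controls-only cohort are all level 0", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 4, n_days = 3, seed = 6)
  co <- simulate_cohort(cfg)
  samples <- build_training_samples(co$recordings)
  expect_gt(nrow(samples), 0)
  expect_true(all(samples$mfsl == 0L))
  expect_true(all(samples$updrs == 0))
})

test_that("grouped split keeps subjects disjoint and near the target share", {
  co <- small_cohort()
  samples <- cached("small_samples", function() {
    build_training_samples(small_cohort()$recordings)
  })
  samples$label <- as.integer(samples$mfsl >= 3)
  for (seed in 1:20) {
    test_ids <- grouped_split(samples, 0.30, seed = seed)
    expect_true(length(test_ids) > 0)
    is_test <- samples$subject_id %in% test_ids
    expect_length(intersect(unique(samples$subject_id[is_test]),
                            unique(samples$subject_id[!is_test])), 0)
  }
  test_ids <- grouped_split(samples, 0.30, seed = 3)
  expect_identical(test_ids, grouped_split(samples, 0.30, seed = 3))
  is_test <- samples$subject_id %in% test_ids
  for (cls in 0:1) {
    frac <- sum(is_test & samples$label == cls) / sum(samples$label == cls)
    expect_gt(frac, 0.15)
    expect_lt(frac, 0.45)
  }
})

test_that("perfectly separable classes reach CV AUC 1, shuffled labels 0.5", {
  set.seed(33)
  n_subj <- 250
  subj <- sprintf("s%03d", seq_len(n_subj))
  mfsl <- rep_len(0:5, n_subj)
  samples <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    data.frame(subject_id = subj[i], group = "PwP", role = "DT",
               timestamp_min = 1:8,
               BKS_M10P = mfsl[i] * 10 + runif(8, 0, 1),
               BKS_M25P = mfsl[i] * 10 + runif(8, 0, 1),
               TA_WM50P_Log = runif(8, 0, 0.1),
               updrs = NA_real_, mfsl = mfsl[i])
  }))
  m <- train_severity_model(samples, seed = 2)
  expect_true(all(m$training_report$cv_roc_auc > 0.999))
  expect_true(all(m$training_report$test_roc_auc > 0.999))

  shuffled <- samples
  shuffled$mfsl <- sample(shuffled$mfsl)
  m0 <- train_severity_model(shuffled, seed = 2)
  expect_true(all(abs(m0$training_report$cv_roc_auc - 0.5) < 0.07))
})

test_that("pca_logistic consumes one BKS component plus the tremor feature", {
  set.seed(34)
  n_subj <- 40
  samples <- do.call(rbind, lapply(seq_len(n_subj), function(i) {
    lev <- (i - 1) %% 6
    data.frame(subject_id = sprintf("s%02d", i), group = "PwP", role = "DT",
               timestamp_min = 1:6,
               BKS_M10P = lev * 8 + rnorm(6),
               BKS_M25P = lev * 8 + rnorm(6),
               TA_WM50P_Log = rnorm(6, sd = 0.1),
               updrs = NA_real_, mfsl = lev)
  }))
  m <- train_severity_model(samples, model_family = "pca_logistic", seed = 4)
  for (clf in m$classifiers) {
    expect_length(clf$rotation, 2)
    expect_named(clf$rotation, c("BKS_M10P", "BKS_M25P"))
    expect_length(clf$coef, 2)   # PC1 + TA_WM50P_Log
  }
  pred <- predict_epoch_mfsl(m, samples)
  expect_true(all(pred >= 0 & pred <= 5, na.rm = TRUE))
})

test_that("per-epoch severity is the sum of the five binary votes", {
  feats <- data.frame(BKS_M10P = c(1, 2), BKS_M25P = c(1, 2),
                      TA_WM50P_Log = c(0, 0))
  expect_identical(predict_epoch_mfsl(make_vote_model(rep(-10, 5)), feats),
                   c(0, 0))
  expect_identical(predict_epoch_mfsl(make_vote_model(rep(10, 5)), feats),
                   c(5, 5))
  mixed <- make_vote_model(c(10, 10, 10, -10, -10))
  expect_identical(predict_epoch_mfsl(mixed, feats), c(3, 3))
  # missing features propagate as NA
  feats$BKS_M10P[2] <- NA
  expect_identical(predict_epoch_mfsl(mixed, feats), c(3, NA))
})

test_that("a threshold with an empty side is a training error", {
  samples <- data.frame(subject_id = rep(sprintf("s%d", 1:20), each = 5),
                        group = "PwP", role = "DT", timestamp_min = 1,
                        BKS_M10P = rnorm(100), BKS_M25P = rnorm(100),
                        TA_WM50P_Log = 0, updrs = NA_real_,
                        mfsl = rep(c(0L, 1L), 50))
  expect_error(train_severity_model(samples, seed = 1),
               "class is absent")
})
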