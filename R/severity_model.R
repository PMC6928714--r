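# Six-level ordinal severity model: MFSL binning of the UPDRS III, the
# bank of 5 threshold binary classifiers, the subject-grouped train/test
# protocol, and per-epoch severity prediction.

#' MFSL binning of the UPDRS III
#'
#' Motor function severity level (MFSL) 0 is a (scale-adjusted) UPDRS III
#' total below `level0_upper`; levels above are separated by `increment`
#' UPDRS III units, with the top level unbounded above.
#'
#' @param level0_upper upper bound of level 0 (default 10).
#' @param increment level width above level 0 (default 12.5).
#' @param n_levels number of levels (default 6).
#' @return list of class `mfsl_binning`.
#' @export
mfsl_binning <- function(level0_upper = 10, increment = 12.5, n_levels = 6) {
  if (increment <= 0 || level0_upper <= 0 || n_levels < 2) {
    stopf("invalid MFSL binning parameters")
  }
  structure(list(level0_upper = level0_upper, increment = increment,
                 n_levels = n_levels), class = "mfsl_binning")
}

#' Decision thresholds of the ordinal classifier bank
#'
#' One threshold per boundary between adjacent severity levels
#' (`n_levels - 1` of them); classifier k separates scores below versus at
#' or above the k-th threshold. With the defaults:
#' 10, 22.5, 35, 47.5, 60.
#'
#' @param binning an [mfsl_binning()].
#' @return numeric vector of UPDRS III thresholds.
#' @export
ordinal_thresholds <- function(binning = mfsl_binning()) {
  binning$level0_upper + binning$increment * (0:(binning$n_levels - 2))
}

#' Map a UPDRS III score to its severity level
#'
#' @param score non-negative (adjusted-scale) UPDRS III total; vectorized.
#' @param binning an [mfsl_binning()].
#' @return integer level in `0:(n_levels - 1)`; a score equal to a
#'   boundary belongs to the level above it.
#' @export
updrs_to_mfsl <- function(score, binning = mfsl_binning()) {
  if (any(score < 0, na.rm = TRUE)) stopf("UPDRS III score must be >= 0")
  thr <- ordinal_thresholds(binning)
  findInterval(score, thr)
}

#' Harmonize older-scale UPDRS III totals with the MDS scale
#'
#' The MDS revision added items so its totals run higher; older-scale
#' totals are corrected by adding 7 points, MDS totals pass unchanged.
#'
#' @param raw_total non-negative total score; vectorized.
#' @param scale_version `"UPDRS"` (older) or `"MDS-UPDRS"`; vectorized.
#' @return adjusted total on the MDS scale.
#' @export
adjust_updrs <- function(raw_total, scale_version) {
  if (any(raw_total < 0, na.rm = TRUE)) stopf("raw total must be >= 0")
  ok <- scale_version %in% c("UPDRS", "MDS-UPDRS")
  if (!all(ok)) stopf("unknown scale version '%s'", scale_version[!ok][1L])
  raw_total + ifelse(scale_version == "UPDRS", 7, 0)
}

#' Build the epoch-level training samples for a cohort
#'
#' Every usable dose-time epoch is labeled with the subject's OFF-state
#' severity level and every usable effect-time epoch with the ON-state
#' level; controls contribute epochs at a nominal dose time (07:00 for
#' model building) and at their weekly-series trough, all labeled level 0.
#'
#' @param recordings list of `pkg_recording`.
#' @param binning an [mfsl_binning()].
#' @param control_dt_minute clock minute of the controls' nominal dose
#'   time (default 420 = 07:00).
#' @param search_start,search_end ET search window, minutes.
#' @return data frame with `subject_id`, `group`, `role` (`"DT"`/`"ET"`),
#'   `timestamp_min`, the selected features, `updrs` (the adjusted score
#'   the label derives from) and `mfsl` (integer class label).
#' @export
build_training_samples <- function(recordings, binning = mfsl_binning(),
                                   control_dt_minute = 420,
                                   search_start = 46, search_end = 90) {
  out <- lapply(recordings, function(r) {
    dw <- tryCatch(
      dose_windows(r, search_start = search_start, search_end = search_end,
                   nominal_dt = if (r$group == "control") control_dt_minute),
      error = function(e) NULL)
    if (is.null(dw)) return(NULL)
    if (r$group == "control") {
      off_adj <- on_adj <- 0
    } else {
      if (is.null(r$clinical)) return(NULL)
      off_adj <- adjust_updrs(r$clinical$updrs_off_raw,
                              r$clinical$scale_version)
      on_adj <- adjust_updrs(r$clinical$updrs_on_raw,
                             r$clinical$scale_version)
    }
    dt_idx <- unlist(dw$dt_windows, use.names = FALSE)
    et_idx <- unlist(dw$et_windows, use.names = FALSE)
    idx <- c(dt_idx, et_idx)
    if (!length(idx)) return(NULL)
    feats <- featurize(r, at = idx, labels = dw$labels,
                       features = "selected")
    role <- rep(c("DT", "ET"), c(length(dt_idx), length(et_idx)))
    updrs <- ifelse(role == "DT", off_adj, on_adj)
    cbind(data.frame(subject_id = r$subject_id, group = r$group,
                     role = role),
          feats[, c("timestamp_min", selected_features())],
          data.frame(updrs = updrs,
                     mfsl = updrs_to_mfsl(updrs, binning)))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[stats::complete.cases(res[, selected_features()]), , drop = FALSE]
}

#' Subject-grouped stratified train/test split
#'
#' Allocates about `test_fraction` of the samples of each binary class to
#' the test set while keeping every subject wholly on one side, so that
#' no subject contributes to both training and testing.
#'
#' @param samples data frame with `subject_id` and a logical/0-1 `label`
#'   column.
#' @param test_fraction target per-class test share (default 0.30).
#' @param seed integer seed (the subject order is randomized).
#' @return character vector of test-set subject ids.
#' @export
grouped_split <- function(samples, test_fraction = 0.30, seed = 1) {
  counts <- table(samples$subject_id, samples$label)
  subjects <- rownames(counts)
  ord <- with_private_seed(seed, sample(subjects))
  total <- colSums(counts)
  target <- test_fraction * total
  in_test <- numeric(ncol(counts))
  test_ids <- character(0)
  for (s in ord) {
    add <- counts[s, ]
    if (all(in_test + add <= target + 0.05 * total + 1)) {
      in_test <- in_test + add
      test_ids <- c(test_ids, s)
    }
  }
  test_ids
}

# Fit one binary classifier. `x` is the standardized feature matrix.
fit_binary <- function(x, y, family, cv_folds, foldid, seed) {
  if (length(unique(y)) < 2L) {
    stopf("training error: a class is absent on one side of the threshold")
  }
  if (family %in% c("logistic", "pca_logistic")) {
    # penalty chosen by CV deviance (strictly lambda-dependent, unlike the
    # rank-based AUC); ROC/PR are computed fold-wise afterwards
    fit <- with_private_seed(seed, {
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                        nfolds = max(cv_folds, 3), foldid = foldid,
                        type.measure = "deviance", keep = TRUE,
                        standardize = FALSE)
    })
    ilam <- match(fit$lambda.min, fit$lambda)
    cv_pred <- fit$fit.preval[, ilam]
    beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
    list(kind = "glmnet", intercept = beta[1L], coef = beta[-1L],
         cv_pred = stats::plogis(cv_pred))
  } else if (family == "svc_rbf") {
    if (!requireNamespace("e1071", quietly = TRUE)) {
      stopf("family 'svc_rbf' requires the e1071 package")
    }
    fit <- with_private_seed(seed, {
      e1071::svm(x, factor(y, levels = c(0, 1)), probability = TRUE,
                 kernel = "radial")
    })
    list(kind = "svm", model = fit, cv_pred = NULL)
  } else if (family == "gradient_boosting") {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stopf("family 'gradient_boosting' requires the xgboost package")
    }
    fit <- with_private_seed(seed, {
      xgboost::xgboost(data = x, label = y, nrounds = 100, max_depth = 3,
                       eta = 0.1, objective = "binary:logistic",
                       verbose = 0, nthread = 1)
    })
    list(kind = "xgb", model = fit, cv_pred = NULL)
  } else {
    stopf("unknown model family '%s'", family)
  }
}

predict_binary <- function(clf, x) {
  switch(clf$kind,
         glmnet = as.numeric(stats::plogis(clf$intercept +
                                           x %*% clf$coef)),
         svm = {
           p <- attr(stats::predict(clf$model, x, probability = TRUE),
                     "probabilities")
           as.numeric(p[, "1"])
         },
         xgb = as.numeric(stats::predict(clf$model, x)),
         stopf("unknown classifier kind"))
}

#' Train the 5-classifier severity model
#'
#' Decomposes the 6-level severity classification into 5 binary problems
#' (classifier k: severity level >= k, equivalently UPDRS III at or above
#' the k-th ordinal threshold). Each classifier gets its own
#' subject-grouped 30% test split and is fit on its training samples with
#' 10-fold cross-validation; features are standardized with training-set
#' statistics only. The default family is an L2-regularized logistic
#' regression whose penalty is tuned in the cross-validation;
#' `pca_logistic` replaces the two collinear BKS percentiles by their
#' first principal component; `svc_rbf` and `gradient_boosting` are
#' optional nonlinear families.
#'
#' @param samples data frame from [build_training_samples()].
#' @param model_family one of `"logistic"`, `"pca_logistic"`,
#'   `"svc_rbf"`, `"gradient_boosting"`.
#' @param binning an [mfsl_binning()].
#' @param features feature columns used (default [selected_features()]).
#' @param test_fraction per-class test share (default 0.30).
#' @param cv_folds cross-validation folds (default 10).
#' @param seed integer seed for splits and fits.
#' @return object of class `severity_model`: the binning, the fitted
#'   classifiers, per-classifier test subjects, and a `training_report`
#'   data frame (cross-validated ROC/PR AUC where available, held-out
#'   test ROC/PR AUC per classifier).
#' @export
train_severity_model <- function(samples, model_family = "logistic",
                                 binning = mfsl_binning(),
                                 features = selected_features(),
                                 test_fraction = 0.30, cv_folds = 10,
                                 seed = 1) {
  thresholds <- ordinal_thresholds(binning)
  classifiers <- vector("list", length(thresholds))
  report <- vector("list", length(thresholds))
  test_subjects <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    lab <- as.integer(samples$mfsl >= k)
    sk <- cbind(samples, label = lab)
    test_ids <- grouped_split(sk, test_fraction, seed + 1000L * k)
    is_test <- sk$subject_id %in% test_ids
    train <- sk[!is_test, , drop = FALSE]
    test <- sk[is_test, , drop = FALSE]
    xtr <- as.matrix(train[, features, drop = FALSE])
    center <- colMeans(xtr)
    scale_ <- apply(xtr, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    xtr <- scale(xtr, center, scale_)
    rotation <- NULL
    if (model_family == "pca_logistic") {
      bks_cols <- intersect(c("BKS_M10P", "BKS_M25P"), features)
      pca <- stats::prcomp(xtr[, bks_cols, drop = FALSE], center = FALSE,
                           scale. = FALSE)
      rotation <- pca$rotation[, 1L]
      xtr <- cbind(PC1 = as.numeric(xtr[, bks_cols, drop = FALSE] %*%
                                      rotation),
                   xtr[, setdiff(features, bks_cols), drop = FALSE])
    }
    foldid <- with_private_seed(seed + 1000L * k + 1L, {
      subj <- unique(train$subject_id)
      fid <- sample(rep_len(seq_len(cv_folds), length(subj)))
      names(fid) <- subj
      unname(fid[train$subject_id])
    })
    clf <- fit_binary(xtr, train$label, model_family, cv_folds, foldid,
                      seed + 1000L * k + 2L)
    clf$threshold <- thresholds[k]
    clf$center <- center
    clf$scale <- scale_
    clf$rotation <- rotation
    classifiers[[k]] <- clf
    test_roc <- test_pr <- NA_real_
    if (nrow(test) && length(unique(test$label)) == 2L) {
      xte <- transform_features(clf,
                                as.matrix(test[, features, drop = FALSE]))
      p_test <- predict_binary(clf, xte)
      test_roc <- roc_auc(p_test, test$label)
      test_pr <- pr_auc(p_test, test$label)
    }
    cv_roc <- cv_pr <- NA_real_
    if (!is.null(clf$cv_pred)) {
      cv_roc <- foldwise_metric(roc_auc, clf$cv_pred, train$label, foldid)
      cv_pr <- foldwise_metric(pr_auc, clf$cv_pred, train$label, foldid)
    }
    report[[k]] <- data.frame(
      classifier = k, threshold = thresholds[k],
      n_train = nrow(train), n_test = nrow(test),
      cv_roc_auc = cv_roc, cv_pr_auc = cv_pr,
      test_roc_auc = test_roc, test_pr_auc = test_pr)
    test_subjects[[k]] <- test_ids
  }
  structure(list(binning = binning, model_family = model_family,
                 features = features, classifiers = classifiers,
                 test_subjects = test_subjects,
                 training_report = do.call(rbind, report)),
            class = "severity_model")
}

# Average a metric over CV folds (prevalidated predictions), skipping
# folds where only one class is present.
foldwise_metric <- function(metric, pred, label, foldid) {
  vals <- vapply(unique(foldid), function(f) {
    in_f <- foldid == f
    if (length(unique(label[in_f])) < 2L) return(NA_real_)
    metric(pred[in_f], label[in_f])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

transform_features <- function(clf, x) {
  x <- scale(x, clf$center, clf$scale)
  if (!is.null(clf$rotation)) {
    bks_cols <- names(clf$rotation)
    x <- cbind(PC1 = as.numeric(x[, bks_cols, drop = FALSE] %*%
                                  clf$rotation),
               x[, setdiff(colnames(x), bks_cols), drop = FALSE])
  }
  x
}

#' @export
print.severity_model <- function(x, ...) {
  cat(sprintf("<severity_model> family %s, %d threshold classifiers\n",
              x$model_family, length(x$classifiers)))
  print(x$training_report, row.names = FALSE)
  invisible(x)
}

#' Per-epoch severity prediction
#'
#' Each of the 5 threshold classifiers casts a hard above/below vote at
#' probability 0.5; the estimated severity level is the number of
#' "at or above" votes, an integer in 0..5. With `probabilities = TRUE`
#' the sum of the 5 class probabilities is returned instead.
#'
#' @param model a `severity_model`.
#' @param feature_table data frame (or matrix) holding the model's
#'   feature columns; rows with missing features yield `NA`.
#' @param probabilities sum soft probabilities instead of hard votes.
#' @return numeric vector of severity estimates, one per row.
#' @export
predict_epoch_mfsl <- function(model, feature_table, probabilities = FALSE) {
  x <- as.matrix(as.data.frame(feature_table)[, model$features,
                                              drop = FALSE])
  ok <- stats::complete.cases(x)
  out <- rep(NA_real_, nrow(x))
  if (!any(ok)) return(out)
  votes <- vapply(model$classifiers, function(clf) {
    p <- predict_binary(clf, transform_features(clf, x[ok, , drop = FALSE]))
    if (probabilities) p else as.numeric(p > 0.5)
  }, numeric(sum(ok)))
  votes <- matrix(votes, nrow = sum(ok))
  out[ok] <- rowSums(votes)
  out
}
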