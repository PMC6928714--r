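# ROC / precision-recall evaluation of the instrumented levodopa response
# against the binary clinical response classes, and the exclusion-scenario
# tables.

#' Area under the ROC curve
#'
#' Computed as the rank statistic (Mann-Whitney form): the probability
#' that a random positive outscores a random negative, ties counted one
#' half. This equals the trapezoidal area under the ROC curve over all
#' thresholds.
#'
#' @param scores numeric scores, larger meaning "more positive".
#' @param labels binary labels (0/1, logical, or a two-level factor).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stopf("ROC AUC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) > 2L) stopf("labels must be binary")
  as.integer(labels == u[length(u)])
}

# Step-wise average precision for one class: walk unique thresholds from
# the highest score down; the area is the sum of precision times recall
# increment at each threshold.
average_precision <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  pos <- sum(labels == 1L)
  if (pos == 0L) stopf("PR AUC undefined: no positive samples")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # block ends per threshold
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Class-averaged area under the precision-recall curve
#'
#' Mean of the two one-vs-rest precision-recall areas: the positive class
#' scored by the scores, the negative class by their negation. Step-wise
#' (uninterpolated) precision integration. Averaging over both classes
#' keeps the metric informative under class imbalance.
#'
#' @inheritParams roc_auc
#' @return class-averaged PR AUC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (!any(labels == 1L) || !any(labels == 0L)) {
    stopf("PR AUC undefined: both classes must be present")
  }
  (average_precision(scores, labels) +
     average_precision(-scores, 1L - labels)) / 2
}

SCENARIOS <- c("all", "exclude_already_on", "exclude_uncertain",
               "exclude_on_and_uncertain", "exclude_on_uncertain_variable")

#' Exclusion-scenario evaluation table
#'
#' Recomputes the ROC and PR AUC of the instrumented response against the
#' binary clinical response class under cumulative exclusion scenarios:
#' all subjects; dropping those flagged already ON; dropping the
#' uncertain zone; both; and additionally dropping excess-variability
#' subjects (amplitude or latency flag). Controls are class 0 throughout;
#' uncertain-zone subjects count as class 1 in scenarios that retain them
#' (their improvement exceeds the insignificance bound). Support counts
#' are reported per class, patients and controls separately.
#'
#' @param results cohort results from [run_ldct_cohort()].
#' @param score_kind `"abs"` (absolute response, levels) or `"pct"`
#'   (percentage response).
#' @return data frame, one row per scenario: `scenario`, `roc_auc`,
#'   `pr_auc` (`NA` when a scenario leaves a single class),
#'   `support_class0`, `support_class0_pwp`, `support_class0_controls`,
#'   `support_class1`, `n`.
#' @export
scenario_table <- function(results, score_kind = c("abs", "pct")) {
  score_kind <- match.arg(score_kind)
  score_col <- if (score_kind == "abs") "abs_delta_pkg" else "pct_delta_pkg"
  r <- results[!is.na(results[[score_col]]) &
                 !is.na(results$abs_delta_updrs), , drop = FALSE]
  r$label <- as.integer(r$abs_delta_updrs > uncertain_zone()$lower - 1)
  r$variable <- isTRUE_vec(r$flag_variable_amplitude) |
    isTRUE_vec(r$flag_variable_latency)
  keep <- list(
    all = rep(TRUE, nrow(r)),
    exclude_already_on = !isTRUE_vec(r$flag_already_on),
    exclude_uncertain = !isTRUE_vec(r$flag_uncertain),
    exclude_on_and_uncertain = !isTRUE_vec(r$flag_already_on) &
      !isTRUE_vec(r$flag_uncertain),
    exclude_on_uncertain_variable = !isTRUE_vec(r$flag_already_on) &
      !isTRUE_vec(r$flag_uncertain) & !r$variable)
  rows <- lapply(SCENARIOS, function(sc) {
    d <- r[keep[[sc]], , drop = FALSE]
    auc_roc <- auc_pr <- NA_real_
    if (length(unique(d$label)) == 2L) {
      auc_roc <- roc_auc(d[[score_col]], d$label)
      auc_pr <- pr_auc(d[[score_col]], d$label)
    }
    data.frame(scenario = sc, roc_auc = auc_roc, pr_auc = auc_pr,
               support_class0 = sum(d$label == 0L),
               support_class0_pwp = sum(d$label == 0L & d$group == "PwP"),
               support_class0_controls = sum(d$label == 0L &
                                               d$group == "control"),
               support_class1 = sum(d$label == 1L), n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Published cohort flow arithmetic
#'
#' Bookkeeping for a screened clinical cohort: subjects screened minus
#' subjects excluded gives the analyzed cohort.
#'
#' @param n_screened,n_excluded subject counts (defaults: the multicentre
#'   levodopa-challenge cohort that motivates the package defaults, 199
#'   screened with 48 exclusions).
#' @return list with `n_screened`, `n_excluded`, `n_included`.
#' @export
cohort_flow <- function(n_screened = 199, n_excluded = 48) {
  if (n_excluded > n_screened) stopf("cannot exclude more than screened")
  list(n_screened = n_screened, n_excluded = n_excluded,
       n_included = n_screened - n_excluded)
}

#' Per-clinic response deltas from published summary statistics
#'
#' Reads a clinic-level summary table (mean OFF and ON UPDRS III per
#' clinic) and adds the absolute and percentage OFF-to-ON response.
#'
#' @param path CSV with columns `clinic`, `updrs_off_mean`,
#'   `updrs_on_mean`; defaults to the summary shipped with the package.
#' @return the table with `abs_delta_updrs` and `pct_delta_updrs` added.
#' @export
cohort_summary_deltas <- function(path = system.file(
  "extdata", "ldct_cohort_summary.csv", package = "wristldct")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$abs_delta_updrs <- tab$updrs_off_mean - tab$updrs_on_mean
  tab$pct_delta_updrs <- tab$abs_delta_updrs / tab$updrs_off_mean * 100
  tab
}
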