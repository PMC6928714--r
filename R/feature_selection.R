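# Mutual-information relevance scoring and JMIM (joint mutual information
# maximization) redundancy-aware feature ranking.
#
# Features are continuous and the target is the discrete 6-level severity
# class, so mutual information is estimated with the nearest-neighbour
# estimator for mixed continuous/discrete variables (Ross 2014 form): for
# each sample the distance to its k-th nearest neighbour within its own
# class defines a radius, and the number of samples of any class inside
# that radius enters a digamma average. Multidimensional distances use the
# max-norm, which keeps the joint estimator consistent with the marginal
# one. Percentile features carry many exact ties, which break k-NN
# estimators, so a tiny seeded jitter is added before distances are
# computed.

knn_mi_core <- function(x, y, k = 6) {
  x <- as.matrix(x)
  n <- nrow(x)
  y <- as.character(y)
  cls <- split(seq_len(n), y)
  small <- vapply(cls, length, integer(1)) < k + 1
  if (any(small)) {
    stopf("class '%s' has fewer than k + 1 = %d samples",
          names(cls)[which(small)[1L]], k + 1)
  }
  n_y <- lengths(cls)[y]
  k_i <- rep(k, n)
  m_i <- numeric(n)
  d_k <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x[, 1L] - x[i, 1L])
    if (ncol(x) > 1L) {
      for (j in 2:ncol(x)) d <- pmax(d, abs(x[, j] - x[i, j]))
    }
    same <- cls[[y[i]]]
    ds <- d[same[same != i]]
    d_k[i] <- sort(ds, partial = k)[k]
    m_i[i] <- sum(d < d_k[i]) - 1L   # neighbours strictly inside, minus self
  }
  mi <- digamma(n) + mean(digamma(k_i)) - mean(digamma(n_y)) -
    mean(digamma(m_i + 1))
  max(0, mi)
}

add_jitter <- function(x, jitter_scale, seed) {
  x <- as.matrix(x)
  if (jitter_scale <= 0) return(x)
  with_private_seed(seed, {
    for (j in seq_len(ncol(x))) {
      rng <- diff(range(x[, j]))
      if (rng == 0) rng <- 1
      x[, j] <- x[, j] + stats::runif(nrow(x), -1, 1) * jitter_scale * rng
    }
    x
  })
}

#' Mutual information between a continuous feature and discrete classes
#'
#' Nearest-neighbour estimate (in nats) of the mutual information between
#' a continuous feature and a discrete class label, clipped at zero (the
#' estimator can go slightly negative under independence).
#'
#' @param feature_values numeric vector.
#' @param class_labels vector of class labels (each represented class
#'   needs at least `k + 1` samples).
#' @param k number of neighbours (default 6).
#' @param jitter_scale tie-breaking jitter as a fraction of the value
#'   range (default 1e-10); set 0 to disable.
#' @param seed seed for the jitter stream.
#' @return list with `mi` (nats), `k_neighbors`.
#' @export
mi_continuous_discrete <- function(feature_values, class_labels, k = 6,
                                   jitter_scale = 1e-10, seed = 1) {
  stopifnot(length(feature_values) == length(class_labels))
  if (any(!is.finite(feature_values))) stopf("feature values must be finite")
  x <- add_jitter(feature_values, jitter_scale, seed)
  list(mi = knn_mi_core(x, class_labels, k), k_neighbors = k)
}

#' Joint mutual information of a feature pair with discrete classes
#'
#' As [mi_continuous_discrete()] but on the 2-dimensional feature (pairs
#' compared under the max-norm).
#'
#' @param feature_pair two-column matrix or data frame.
#' @inheritParams mi_continuous_discrete
#' @return list with `mi` (nats), `k_neighbors`.
#' @export
joint_mi <- function(feature_pair, class_labels, k = 6,
                     jitter_scale = 1e-10, seed = 1) {
  x <- as.matrix(feature_pair)
  stopifnot(ncol(x) == 2L, nrow(x) == length(class_labels))
  if (any(!is.finite(x))) stopf("feature values must be finite")
  x <- add_jitter(x, jitter_scale, seed)
  list(mi = knn_mi_core(x, class_labels, k), k_neighbors = k)
}

#' Greedy JMIM ranking of candidate features
#'
#' Picks first the feature with maximal marginal mutual information with
#' the class labels, then iteratively adds the candidate whose minimum
#' joint mutual information with any already selected feature is maximal.
#' This favours candidates that are both relevant and non-redundant. Ties
#' are broken by input column order.
#'
#' @param candidates data frame or matrix of candidate features (>= 2
#'   columns).
#' @inheritParams mi_continuous_discrete
#' @return data frame with `feature`, `rank` and `score` (the criterion
#'   value at selection: marginal MI for the first feature, the min-joint
#'   MI criterion afterwards), plus a `marginal_mi` column.
#' @export
jmim_rank <- function(candidates, class_labels, k = 6,
                      jitter_scale = 1e-10, seed = 1) {
  x <- as.data.frame(candidates)
  if (ncol(x) < 2L) stopf("need at least 2 candidate features")
  feats <- names(x)
  marg <- vapply(feats, function(f) {
    mi_continuous_discrete(x[[f]], class_labels, k, jitter_scale, seed)$mi
  }, numeric(1))
  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  first <- remaining[which.max(marg[remaining])]
  selected <- first
  scores <- marg[[first]]
  remaining <- setdiff(remaining, first)
  jmi_cache <- new.env(parent = emptyenv())
  jmi <- function(f, s) {
    key <- paste(sort(c(f, s)), collapse = "\r")
    if (is.null(jmi_cache[[key]])) {
      jmi_cache[[key]] <- joint_mi(cbind(x[[f]], x[[s]]), class_labels, k,
                                   jitter_scale, seed)$mi
    }
    jmi_cache[[key]]
  }
  while (length(remaining)) {
    crit <- vapply(remaining, function(f) {
      min(vapply(selected, function(s) jmi(f, s), numeric(1)))
    }, numeric(1))
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, crit[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  data.frame(feature = selected, rank = seq_along(selected),
             score = unname(scores),
             marginal_mi = unname(marg[selected]))
}
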