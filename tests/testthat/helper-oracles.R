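# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately take different computational routes
# from the implementation (library quantile types, O(n^2) pair counting,
# explicit threshold walks, histogram plug-ins).

# Weighted percentile without sorting: scan candidate values and pick the
# smallest whose at-or-below weight share reaches q/100.
oracle_weighted_percentile <- function(x, w, q) {
  if (sum(w) <= 0) return(NA_real_)
  cand <- sort(unique(x))
  for (v in cand) {
    if (sum(w[x <= v]) / sum(w) >= q / 100) return(v)
  }
  cand[length(cand)]
}

# Unweighted nearest-rank percentile via the stats library (type 1 is the
# inverted-CDF definition).
oracle_percentile <- function(x, q) {
  unname(stats::quantile(x, q / 100, type = 1))
}

# ROC AUC as explicit pairwise concordance with ties counted one half.
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Average precision by an explicit walk over every distinct threshold.
oracle_average_precision <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

oracle_pr_auc <- function(scores, labels) {
  (oracle_average_precision(scores, labels) +
     oracle_average_precision(-scores, 1 - labels)) / 2
}

# Plug-in discrete MI (nats) after binning the continuous variable.
oracle_plugin_mi <- function(x, y, n_bins = 60) {
  bx <- cut(x, breaks = n_bins)
  tab <- table(bx, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  tot <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  tot
}

# Analytic MI (nats) of a balanced two-class Gaussian location model:
# X | Y = k ~ N(mu_k, 1). MI = H(X) - H(X | Y), with the mixture entropy
# obtained by numerical integration.
oracle_gaussian_location_mi <- function(delta) {
  dens <- function(x) {
    0.5 * stats::dnorm(x, -delta / 2) + 0.5 * stats::dnorm(x, delta / 2)
  }
  integrand <- function(x) {
    f <- dens(x)
    ifelse(f > 0, -f * log(f), 0)
  }
  h_mix <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-9)$value
  h_cond <- 0.5 * log(2 * pi * exp(1))
  h_mix - h_cond
}
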