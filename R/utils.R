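# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Nearest-rank percentile
#'
#' Smallest element of `x` whose rank divided by `length(x)` reaches
#' `q / 100` (the inverted-CDF convention). Used by all unweighted moving
#' percentiles so that substituting uniform weights into the weighted
#' statistic reproduces it exactly.
#'
#' @param x numeric vector (no NA).
#' @param q percentile in (0, 100).
#' @return a single numeric value.
#' @keywords internal
nearest_rank_percentile <- function(x, q) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, partial = NULL)[max(1L, ceiling(q / 100 * n))]
}

#' Weighted percentile by cumulative normalized weight
#'
#' Values are sorted ascending carrying their weights; the result is the
#' smallest value whose cumulative normalized weight reaches `q / 100`.
#'
#' @param x numeric vector.
#' @param w non-negative weights, same length as `x`.
#' @param q percentile in (0, 100).
#' @return a single numeric value, or `NA` when the total weight is zero.
#' @keywords internal
weighted_percentile <- function(x, w, q) {
  if (length(x) == 0L) return(NA_real_)
  tot <- sum(w)
  if (tot <= 0) return(NA_real_)
  o <- order(x)
  cw <- cumsum(w[o]) / tot
  x[o][which(cw >= q / 100)[1L]]
}

#' Triangular kernel weights for a centered window
#'
#' Weight is maximal at the window center and declines linearly and
#' symmetrically on each side, reaching zero one epoch outside the window
#' (so every in-window epoch keeps a positive weight).
#'
#' @param window_epochs odd window length.
#' @return numeric vector of length `window_epochs`, maximum 1 at center.
#' @keywords internal
triangular_weights <- function(window_epochs) {
  h <- (window_epochs - 1L) %/% 2L
  (h + 1 - abs(seq(-h, h))) / (h + 1)
}

# Truncated normal draws by inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Two-state Markov bout process with stationary occupancy `rate` and mean
# bout length `mean_len` epochs; initialized from the stationary law so the
# expected flagged fraction equals `rate` exactly.
markov_bouts <- function(n, rate, mean_len) {
  if (n <= 0L) return(logical(0))
  if (rate <= 0) return(rep(FALSE, n))
  if (rate >= 1) return(rep(TRUE, n))
  p10 <- 1 / mean_len                      # leave bout
  p01 <- rate * p10 / (1 - rate)           # enter bout
  p01 <- min(p01, 1)
  s <- logical(n)
  u <- stats::runif(n)
  s[1L] <- u[1L] < rate
  if (n > 1L) {
    for (i in 2:n) {
      s[i] <- if (s[i - 1L]) u[i] > p10 else u[i] < p01
    }
  }
  s
}

# Evaluate an expression with a private RNG stream, restoring the caller's.
with_private_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
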