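#' Pooled sensitivity of a 2x2 table
#'
#' Sensitivity against the reference standard, `tp / (tp + fn)`, pooling all
#' analysis units as if independent. For clustered data this point estimate
#' is valid (it equals the ratio-of-totals estimator) but its naive binomial
#' variance is not; see [cluster_sensitivity()].
#'
#' @param table a [tvt_table()].
#' @return proportion in \[0, 1\].
#' @export
pooled_sensitivity <- function(table) {
  stopifnot(inherits(table, "tvt_table"))
  n <- table$tp + table$fn
  if (n == 0L) stop("sensitivity undefined: no reference-positive units (tp + fn = 0)")
  table$tp / n
}

#' Pooled specificity of a 2x2 table
#' @param table a [tvt_table()].
#' @return proportion `tn / (tn + fp)`.
#' @export
pooled_specificity <- function(table) {
  stopifnot(inherits(table, "tvt_table"))
  n <- table$tn + table$fp
  if (n == 0L) stop("specificity undefined: no reference-negative units (tn + fp = 0)")
  table$tn / n
}

.new_estimate_ci <- function(estimate, lower, upper, level, method,
                             x = NULL, n = NULL, se = NULL,
                             n_clusters = NULL) {
  stopifnot(lower <= estimate + 1e-12, estimate <= upper + 1e-12)
  structure(list(estimate = estimate,
                 lower = max(0, min(lower, 1)),
                 upper = max(0, min(upper, 1)),
                 level = level, method = method, x = x, n = n, se = se,
                 n_clusters = n_clusters),
            class = "estimate_ci")
}

#' @export
print.estimate_ci <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f (%d%% CI: %.*f-%.*f) [%s%s]\n",
              digits, round_half_up(x$estimate, digits),
              round(100 * x$level),
              digits, round_half_up(x$lower, digits),
              digits, round_half_up(x$upper, digits),
              x$method,
              if (!is.null(x$n_clusters)) sprintf(", K=%d", x$n_clusters) else ""))
  invisible(x)
}

#' Round half away from zero
#'
#' Display rounding used throughout the reports; unlike [base::round()] it
#' never rounds to even, so 0.975 at 2 dp is 0.98.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval obtained by inverting the binomial CDF, computed via
#' beta-distribution quantiles: the lower bound is the `alpha/2` quantile of
#' `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper bound the
#' `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when `x = n`). At
#' `x = n` the lower bound has the closed form `(alpha/2)^(1/n)`.
#'
#' @param x number of successes.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return An `estimate_ci` with method `"clopper_pearson"`.
#' @export
clopper_pearson_ci <- function(x, n, level = 0.95) {
  .check_xn(x, n, level)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  .new_estimate_ci(x / n, lower, upper, level, "clopper_pearson", x = x, n = n)
}

#' Wilson score confidence interval
#'
#' The score interval from inverting the normal test on the null standard
#' error; its bounds never leave \[0, 1\] and it is the usual asymptotic
#' companion to the exact interval.
#'
#' @inheritParams clopper_pearson_ci
#' @return An `estimate_ci` with method `"wilson"`.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  .check_xn(x, n, level)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  .new_estimate_ci(p, max(0, center - half), min(1, center + half),
                   level, "wilson", x = x, n = n)
}

.check_xn <- function(x, n, level) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop("need integers 0 <= x <= n with n >= 1")
  }
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("confidence level must lie in (0, 1)")
  }
  invisible(TRUE)
}

# Ratio-of-totals proportion with cluster-robust (sandwich) variance.
# p-hat = sum(x) / sum(n); var = K/(K-1) * sum((x_i - p*n_i)^2) / (sum n)^2.
# Clusters with n_i = 0 carry no information and are dropped first.
.cluster_proportion <- function(x, n, level, method,
                                scale = c("identity", "logit")) {
  scale <- match.arg(scale)
  keep <- n > 0
  x <- x[keep]; n <- n[keep]
  k <- length(n)
  if (k < 2L) stop("cluster-robust variance needs >= 2 informative clusters")
  p <- sum(x) / sum(n)
  v <- (k / (k - 1)) * sum((x - p * n)^2) / sum(n)^2
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (scale == "logit" && p > 0 && p < 1 && se > 0) {
    lo <- log(p / (1 - p))
    se_lo <- se / (p * (1 - p))
    bounds <- stats::plogis(lo + c(-1, 1) * z * se_lo)
  } else {
    if (scale == "logit") {
      warning("logit-scale interval undefined at estimate 0, 1 or zero variance; using identity scale")
    }
    bounds <- pmin(1, pmax(0, p + c(-1, 1) * z * se))
  }
  .new_estimate_ci(p, bounds[1], bounds[2], level, method,
                   x = sum(x), n = sum(n), se = se, n_clusters = k)
}

#' Cluster-robust sensitivity estimate
#'
#' Ratio-of-totals sensitivity over patient clusters with a sandwich
#' (between-cluster empirical) variance: with `K` informative clusters
#' (those containing at least one diseased site), the variance is
#' `K/(K-1) * sum((x_i - p*n_i)^2) / (sum n_i)^2`, where `x_i` of the `n_i`
#' diseased sites in cluster `i` were detected. Within-cluster correlation
#' inflates this variance relative to the naive binomial one, which is the
#' point: treating correlated gland calls as independent yields misleadingly
#' small standard errors. With all clusters of size 1 the formula reduces to
#' the binomial variance with an `K/(K-1)` correction,
#' `p(1-p)/(K-1)`.
#'
#' @param summaries a [cluster_summaries()] data.frame.
#' @param test `"A"` or `"B"`.
#' @param level confidence level.
#' @param scale `"identity"` (normal interval clamped to \[0,1\]) or
#'   `"logit"` (delta-method interval on the log-odds scale, useful near 1).
#' @return An `estimate_ci` with method `"cluster_sandwich"`.
#' @export
cluster_sensitivity <- function(summaries, test = c("A", "B"), level = 0.95,
                                scale = c("identity", "logit")) {
  test <- match.arg(test)
  x <- if (test == "A") summaries$x_a else summaries$x_b
  .cluster_proportion(x, summaries$n_pos, level, "cluster_sandwich", scale)
}

#' Cluster-robust specificity estimate
#'
#' Same estimator as [cluster_sensitivity()] applied to correct-negative
#' calls at non-diseased sites: `(m_i - f_i)` of `m_i`.
#'
#' @inheritParams cluster_sensitivity
#' @return An `estimate_ci`.
#' @export
cluster_specificity <- function(summaries, test = c("A", "B"), level = 0.95,
                                scale = c("identity", "logit")) {
  test <- match.arg(test)
  f <- if (test == "A") summaries$f_a else summaries$f_b
  .cluster_proportion(summaries$m_neg - f, summaries$m_neg, level,
                      "cluster_sandwich", scale)
}
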