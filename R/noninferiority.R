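#' Cluster-robust sensitivity difference of two paired tests
#'
#' Estimates `d = Se(B) - Se(A)` by the difference of ratio-of-totals
#' sensitivities over patient clusters, with a sandwich standard error from
#' the between-cluster variation of the paired detection differences:
#' `d_hat = sum(x_b - x_a) / sum(n)` over the `K` clusters holding diseased
#' sites, and `se^2 = K/(K-1) * sum(((x_bi - x_ai) - d_hat * n_i)^2) /
#' (sum n)^2`. Because both tests are scored on the same glands, the paired
#' construction absorbs the within-gland correlation of the two tests as
#' well as the within-patient clustering.
#'
#' @param summaries a [cluster_summaries()] data.frame.
#' @return list with `d_hat`, `se`, `n_clusters`.
#' @export
sensitivity_difference <- function(summaries) {
  keep <- summaries$n_pos > 0
  x_a <- summaries$x_a[keep]
  x_b <- summaries$x_b[keep]
  n <- summaries$n_pos[keep]
  k <- length(n)
  if (k < 2L) stop("sensitivity difference needs >= 2 informative clusters")
  d <- sum(x_b - x_a) / sum(n)
  e <- (x_b - x_a) - d * n
  se <- sqrt((k / (k - 1)) * sum(e^2) / sum(n)^2)
  if (se == 0) {
    warning("zero between-cluster variance: the two tests agree on every cluster up to the common difference")
  }
  list(d_hat = d, se = se, n_clusters = k)
}

#' Non-inferiority test for a sensitivity difference
#'
#' One-sided test of `H0: d <= delta` against `H1: d > delta` for
#' `d = Se(B) - Se(A)`, where `delta < 0` is the largest acceptable
#' sensitivity deficit of test B. Uses the cluster-robust estimate from
#' [sensitivity_difference()] and a normal reference:
#' `z = (d_hat - delta) / se`, one-sided `p = 1 - pnorm(z)`, and a
#' companion two-sided CI `d_hat +/- z_{(1+ci_level)/2} * se`. With the
#' matched construction `ci_level = 1 - 2*alpha` (the default), the CI rule
#' "lower bound above `delta`" and the p-value rule `p < alpha` give the
#' same verdict on every input.
#'
#' The sign convention makes `z` positive when the data favour
#' non-inferiority; `abs(z)` is reported alongside since published analyses
#' differ in orientation.
#'
#' @param summaries a [cluster_summaries()] data.frame; alternatively pass
#'   `d_hat` and `se` directly (then `summaries` may be `NULL`).
#' @param delta non-inferiority margin, a negative proportion
#'   (default -0.10).
#' @param alpha one-sided significance level in (0, 0.5), default 0.05.
#' @param ci_level level of the companion CI, default `1 - 2 * alpha`
#'   (0.90 at the default alpha).
#' @param d_hat,se optional pre-computed difference and cluster-robust SE.
#' @param n_clusters optional cluster count for reporting.
#' @return A `noninferiority_result`: `delta`, `d_hat`, `se`, `z`,
#'   `p_one_sided`, `ci_lower`, `ci_upper`, `ci_level`, `alpha`,
#'   `noninferior`, `n_clusters`, `degenerate` (TRUE when `se = 0` and the
#'   verdict falls back to the sign of `d_hat - delta`).
#' @export
noninferiority_test <- function(summaries = NULL, delta = -0.10,
                                alpha = 0.05, ci_level = 1 - 2 * alpha,
                                d_hat = NULL, se = NULL, n_clusters = NULL) {
  if (!is.numeric(delta) || delta >= 0) {
    stop("non-inferiority margin delta must be negative for a difference B - A")
  }
  if (alpha <= 0 || alpha >= 0.5) stop("one-sided alpha must lie in (0, 0.5)")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  if (is.null(d_hat) || is.null(se)) {
    est <- sensitivity_difference(summaries)
    d_hat <- est$d_hat; se <- est$se; n_clusters <- est$n_clusters
  }
  if (se < 0 || is.na(se)) stop("invalid standard error")
  if (se == 0) {
    warning("zero standard error: verdict from the sign of d_hat - delta, no z statistic")
    return(structure(list(delta = delta, d_hat = d_hat, se = 0,
                          z = NA_real_, p_one_sided = NA_real_,
                          ci_lower = d_hat, ci_upper = d_hat,
                          ci_level = ci_level, alpha = alpha,
                          noninferior = d_hat > delta,
                          n_clusters = n_clusters, degenerate = TRUE),
                     class = "noninferiority_result"))
  }
  z <- (d_hat - delta) / se
  p <- stats::pnorm(z, lower.tail = FALSE)
  zq <- stats::qnorm((1 + ci_level) / 2)
  ci <- d_hat + c(-1, 1) * zq * se
  structure(list(delta = delta, d_hat = d_hat, se = se, z = z,
                 p_one_sided = p, ci_lower = ci[1], ci_upper = ci[2],
                 ci_level = ci_level, alpha = alpha,
                 noninferior = ci[1] > delta,
                 n_clusters = n_clusters, degenerate = FALSE),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat("Non-inferiority test for sensitivity difference (B - A)\n")
  cat(sprintf("  margin delta = %.3f, one-sided alpha = %.3f\n", x$delta, x$alpha))
  cat(sprintf("  d_hat = %.4f, cluster-robust SE = %.4f%s\n", x$d_hat, x$se,
              if (!is.null(x$n_clusters)) sprintf(" (K = %d clusters)", x$n_clusters) else ""))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate variance: verdict by sign of d_hat - delta\n")
  } else {
    cat(sprintf("  z = %.3f (|z| = %.3f), one-sided p = %.4g\n", x$z, abs(x$z),
                x$p_one_sided))
    cat(sprintf("  %d%% CI: (%.3f, %.3f)\n", round(100 * x$ci_level),
                x$ci_lower, x$ci_upper))
  }
  cat(sprintf("  verdict: %s\n",
              if (x$noninferior) "NON-INFERIOR (CI lower bound above margin)"
              else "non-inferiority NOT demonstrated"))
  invisible(x)
}
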