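.new_test_result <- function(statistic, df, p_value, method,
                             sidedness = "two", ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   method = method, sidedness = sidedness), list(...)),
            class = "cs_test_result")
}

#' @export
print.cs_test_result <- function(x, ...) {
  cat(sprintf("%s: %s%sp = %.4g (%s-sided)\n", x$method,
              if (!is.null(x$statistic) && !is.na(x$statistic))
                sprintf("statistic = %.4g, ", x$statistic) else "",
              if (!is.null(x$df) && !is.na(x$df)) sprintf("df = %d, ", x$df) else "",
              x$p_value, x$sidedness))
  invisible(x)
}

#' McNemar test of marginal homogeneity
#'
#' Compares the marginal positivity of two tests applied to the same units,
#' driven by the discordant cells `b` (A+/B-) and `c` (A-/B+):
#' \describe{
#'   \item{`exact`}{two-sided exact binomial test of `b` against
#'     `Binomial(b + c, 1/2)`, i.e. `min(1, 2 * P(X <= min(b, c)))`.}
#'   \item{`chi2`}{chi-square statistic `(b - c)^2 / (b + c)`, 1 df.}
#'   \item{`chi2_cc`}{continuity-corrected statistic
#'     `(|b - c| - 1)^2 / (b + c)`.}
#' }
#' Valid only for independent pairs; with patient clusters use
#' [cluster_mcnemar()].
#'
#' @param table a [agreement_table()] (or [method_agreement()] output).
#' @param variant `"exact"`, `"chi2"` or `"chi2_cc"`.
#' @return A test result with statistic (chi-square variants), df and
#'   p-value.
#' @export
mcnemar_test <- function(table, variant = c("exact", "chi2", "chi2_cc")) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "method_agreement"))
  b <- table$b; c <- table$c
  nd <- b + c
  if (variant == "exact") {
    if (nd == 0L) {
      warning("no discordant pairs; exact McNemar p = 1")
      return(.new_test_result(NA_real_, NA_integer_, 1, "mcnemar_exact",
                              b = b, c = c))
    }
    p <- min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    return(.new_test_result(NA_real_, NA_integer_, p, "mcnemar_exact",
                            b = b, c = c))
  }
  if (nd == 0L) stop("chi-square McNemar degenerate: no discordant pairs (b + c = 0)")
  stat <- if (variant == "chi2") (b - c)^2 / nd else (abs(b - c) - 1)^2 / nd
  .new_test_result(stat, 1L, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   paste0("mcnemar_", variant), b = b, c = c)
}

#' Cluster-adjusted McNemar test
#'
#' Marginal-homogeneity test for two tests on clustered matched pairs. The
#' naive McNemar test counts every gland site as independent, which
#' understates the variance when detections within a patient are positively
#' correlated. This version tests the difference of the two ratio-of-totals
#' sensitivities with a between-cluster empirical variance:
#' `D = (sum x_a - sum x_b) / sum n` over the `K` clusters with diseased
#' sites, residuals `e_i = (x_ai - x_bi) - D * n_i`, variance
#' `V = K/(K-1) * sum(e_i^2) / (sum n)^2`, statistic `D^2 / V` referred to
#' chi-square with 1 df. With single-site clusters and balanced discordances
#' (`b = c`) the statistic is exactly 0, agreeing with classical McNemar.
#'
#' @param summaries a [cluster_summaries()] data.frame.
#' @return A test result with method `"mcnemar_cluster_adjusted"`; carries
#'   the estimated difference `d_hat` and `n_clusters`.
#' @export
cluster_mcnemar <- function(summaries) {
  keep <- summaries$n_pos > 0
  x_a <- summaries$x_a[keep]
  x_b <- summaries$x_b[keep]
  n <- summaries$n_pos[keep]
  k <- length(n)
  if (k < 2L) stop("cluster-adjusted McNemar needs >= 2 informative clusters")
  d <- (sum(x_a) - sum(x_b)) / sum(n)
  e <- (x_a - x_b) - d * n
  v <- (k / (k - 1)) * sum(e^2) / sum(n)^2
  if (v == 0) {
    if (d == 0) {
      return(.new_test_result(0, 1L, 1, "mcnemar_cluster_adjusted",
                              d_hat = 0, n_clusters = k))
    }
    stop("degenerate variance: zero between-cluster variation with nonzero difference")
  }
  stat <- d^2 / v
  .new_test_result(stat, 1L, stats::pchisq(stat, df = 1, lower.tail = FALSE),
                   "mcnemar_cluster_adjusted", d_hat = d, n_clusters = k)
}
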