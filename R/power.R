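#' Monte-Carlo operating characteristics of the non-inferiority test
#'
#' For each configuration in `grid`, simulates `n_reps` cohorts, runs
#' [noninferiority_test()] on their cluster summaries and records the
#' fraction of runs declaring non-inferiority. At a true sensitivity
#' difference equal to the margin this fraction is the type-I error of the
#' one-sided test; at larger true differences it is power. Degenerate
#' replicates (zero cluster-robust variance, e.g. perfect detection by both
#' tests) fall back to the sign rule of [noninferiority_test()] and are
#' counted and reported.
#'
#' @param grid a [sim_config()] or list of them.
#' @param delta non-inferiority margin (default -0.10).
#' @param alpha one-sided level (default 0.05).
#' @param n_reps replicates per configuration, >= 100.
#' @param seed master seed; the full grid is reproducible from it.
#' @return data.frame of class `power_grid_result`: one row per
#'   configuration with the design parameters, `true_diff`
#'   (`se_b - se_a`), `n_reps`, `rejection_rate`,
#'   `mc_se` (`sqrt(r(1-r)/n_reps)`) and `n_degenerate`; `seed`, `alpha`
#'   and `delta` are carried as attributes.
#' @export
run_power_grid <- function(grid, delta = -0.10, alpha = 0.05,
                           n_reps = 1000, seed = 1L) {
  if (inherits(grid, "sim_config")) grid <- list(grid)
  if (!length(grid) || !all(vapply(grid, inherits, TRUE, "sim_config"))) {
    stop("grid must be a sim_config or a non-empty list of sim_config objects")
  }
  if (!is.numeric(n_reps) || n_reps < 100) {
    stop("n_reps must be >= 100 for meaningful Monte-Carlo rates")
  }
  n_reps <- as.integer(n_reps)
  set.seed(seed)
  rows <- lapply(grid, function(cfg) {
    rej <- 0L; degen <- 0L
    for (r in seq_len(n_reps)) {
      s <- .simulate_summaries(cfg)
      res <- suppressWarnings(
        noninferiority_test(s, delta = delta, alpha = alpha)
      )
      if (res$degenerate) degen <- degen + 1L
      if (res$noninferior) rej <- rej + 1L
    }
    rate <- rej / n_reps
    data.frame(n_patients = cfg$n_patients, se_a = cfg$se_a,
               se_b = cfg$se_b, icc = cfg$icc, rho_ab = cfg$rho_ab,
               rho_patient = cfg$rho_patient,
               true_diff = cfg$se_b - cfg$se_a, n_reps = n_reps,
               rejection_rate = rate,
               mc_se = sqrt(rate * (1 - rate) / n_reps),
               n_degenerate = degen)
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  attr(out, "delta") <- delta
  class(out) <- c("power_grid_result", "data.frame")
  out
}

#' Monte-Carlo size of naive versus cluster-adjusted McNemar
#'
#' Simulates cohorts under marginal homogeneity of the two tests
#' (`se_a = se_b` in `config`) and reports the empirical rejection rate of
#' the naive chi-square McNemar test (every gland counted as an independent
#' pair) and of [cluster_mcnemar()], both at level `alpha`. When detections
#' within a patient are correlated and the two tests' patient effects are
#' not identical, the naive test rejects too often while the adjusted test
#' holds its level.
#'
#' @param config a [sim_config()]; the null requires `se_a == se_b`.
#' @param n_reps number of simulated cohorts.
#' @param alpha two-sided level (default 0.05).
#' @param seed RNG seed.
#' @return named vector with components `naive`, `adjusted` (rejection
#'   rates) and `n_reps`.
#' @export
mcnemar_size_study <- function(config, n_reps = 1000, alpha = 0.05,
                               seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$se_a != config$se_b) {
    stop("size study requires the marginal-homogeneity null: se_a == se_b")
  }
  if (n_reps < 100) stop("n_reps must be >= 100")
  set.seed(seed)
  rej_naive <- 0L; rej_adj <- 0L
  for (r in seq_len(n_reps)) {
    s <- .simulate_summaries(config)
    b <- sum(s$disc_b); c <- sum(s$disc_c)
    if (b + c > 0) {
      naive_p <- stats::pchisq((b - c)^2 / (b + c), df = 1,
                               lower.tail = FALSE)
      rej_naive <- rej_naive + as.integer(naive_p < alpha)
    }
    adj_p <- tryCatch(cluster_mcnemar(s)$p_value, error = function(e) 1)
    rej_adj <- rej_adj + as.integer(adj_p < alpha)
  }
  c(naive = rej_naive / n_reps, adjusted = rej_adj / n_reps,
    n_reps = n_reps)
}
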