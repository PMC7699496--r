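#' Configuration for the clustered paired-cohort generator
#'
#' Defines the data-generating process the analyses assume: patients carry 1
#' or 2 diseased glands among a fixed set of quadrant sites; a
#' beta-distributed per-patient detection propensity induces the
#' intracluster correlation; the two tests' detections at a diseased gland
#' are a correlated Bernoulli pair (Gaussian copula); non-diseased sites
#' yield rare independent false-positive calls.
#'
#' Defaults mirror a 60-patient parathyroid localization trial: 4 quadrant
#' sites per patient, 10% of patients with a second diseased gland, per-gland
#' sensitivities around 0.85 and false-positive rates around 2% per
#' non-diseased site.
#'
#' @param n_patients number of patient clusters (default 60).
#' @param sites_per_patient quadrant sites per patient (default 4; must be
#'   >= 2 so a second gland has a home).
#' @param p_two_glands probability a patient harbours two diseased glands
#'   rather than one (default 0.1, i.e. 6 of 60 patients in expectation).
#' @param se_a,se_b marginal per-gland detection probabilities of tests A
#'   and B (default 0.85 each).
#' @param fp_a,fp_b per-non-diseased-site false-positive probabilities
#'   (default 0.02 each, roughly 4 calls in 165 sites).
#' @param icc intracluster correlation of detection outcomes within a
#'   patient, in \[0, 1); induced by a beta-distributed patient propensity
#'   with mean `se` and variance `icc * se * (1 - se)` (default 0.3).
#' @param rho_ab within-gland Gaussian-copula correlation between the two
#'   tests' detections, in \[0, 1) (default 0.4).
#' @param rho_patient correlation between the two tests' patient-level
#'   propensity quantiles, in \[0, 1\]; 1 (default) means a single shared
#'   patient effect drives both tests, smaller values let a patient be
#'   "hard" for one test but not the other.
#' @param seed default RNG seed used by [simulate_cohort()] when none is
#'   passed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 60, sites_per_patient = 4,
                       p_two_glands = 0.1, se_a = 0.85, se_b = 0.85,
                       fp_a = 0.02, fp_b = 0.02, icc = 0.3, rho_ab = 0.4,
                       rho_patient = 1, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              sites_per_patient = as.integer(sites_per_patient),
              p_two_glands = as.numeric(p_two_glands),
              se_a = as.numeric(se_a), se_b = as.numeric(se_b),
              fp_a = as.numeric(fp_a), fp_b = as.numeric(fp_b),
              icc = as.numeric(icc), rho_ab = as.numeric(rho_ab),
              rho_patient = as.numeric(rho_patient), seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1")
  if (cfg$sites_per_patient < 2L) {
    stop("sites_per_patient must be >= 2 to accommodate two diseased glands")
  }
  if (cfg$sites_per_patient > length(QUADRANT_SITES)) {
    stop("sites_per_patient cannot exceed the ", length(QUADRANT_SITES),
         " quadrant labels")
  }
  probs <- c(p_two_glands = cfg$p_two_glands, se_a = cfg$se_a,
             se_b = cfg$se_b, fp_a = cfg$fp_a, fp_b = cfg$fp_b)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0, 1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (cfg$icc < 0 || cfg$icc >= 1) {
    stop("icc must lie in [0, 1): the beta-propensity construction needs ",
         "a proper mixing distribution")
  }
  if (cfg$rho_ab < 0 || cfg$rho_ab >= 1) {
    stop("rho_ab must lie in [0, 1): a Gaussian copula at rho = 1 forces ",
         "comonotone calls, the upper Frechet bound, which is only ",
         "attainable for equal marginals")
  }
  if (cfg$rho_patient < 0 || cfg$rho_patient > 1) {
    stop("rho_patient must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %s = %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read a simulation configuration from YAML or JSON
#' @param path file with fields named as in [sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(sim_config, fields)
}

# beta parameters with mean mu and ICC rho: rho = 1 / (alpha + beta + 1)
.beta_shapes <- function(mu, rho) {
  s <- (1 - rho) / rho
  c(alpha = mu * s, beta = (1 - mu) * s)
}

#' Simulate a clustered paired diagnostic cohort
#'
#' Draws one cohort from the process described in [sim_config()]:
#' \enumerate{
#'   \item per patient, 1 or 2 diseased glands, placed uniformly without
#'     replacement among the quadrant sites;
#'   \item a patient-level pair of propensity quantiles (bivariate normal
#'     copula with correlation `rho_patient`) mapped through beta quantile
#'     functions so that test-specific per-gland detection probabilities
#'     have mean `se` and intracluster correlation `icc`;
#'   \item per diseased gland, a correlated Bernoulli pair for the two
#'     tests via a Gaussian copula with correlation `rho_ab`;
#'   \item per non-diseased site, independent false positives at the
#'     configured rates.
#' }
#' Fully deterministic for a given seed.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A gland-level [as_cohort()] cohort.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients
  s <- config$sites_per_patient
  pid <- sprintf("P%04d", seq_len(n))

  ## diseased gland placement
  g <- 1L + stats::rbinom(n, 1L, config$p_two_glands)
  s1 <- sample.int(s, n, replace = TRUE)
  shift <- sample.int(s - 1L, n, replace = TRUE)
  s2 <- ((s1 - 1L + shift) %% s) + 1L     # a site distinct from s1
  truth <- matrix(0L, n, s)
  truth[cbind(seq_len(n), s1)] <- 1L
  two <- which(g == 2L)
  truth[cbind(two, s2[two])] <- 1L

  ## patient propensities
  za <- stats::rnorm(n)
  zb <- config$rho_patient * za +
    sqrt(1 - config$rho_patient^2) * stats::rnorm(n)
  propensity <- function(z, mu) {
    if (config$icc == 0) return(rep(mu, n))
    if (mu == 0 || mu == 1) return(rep(mu, n))
    sh <- .beta_shapes(mu, config$icc)
    stats::qbeta(stats::pnorm(z), sh["alpha"], sh["beta"])
  }
  p_a <- propensity(za, config$se_a)
  p_b <- propensity(zb, config$se_b)

  ## detections at diseased glands (Gaussian copula within gland)
  idx <- which(truth == 1L)            # column-major indices into n x s
  gl_patient <- ((idx - 1L) %% n) + 1L
  ng <- length(idx)
  u1 <- stats::rnorm(ng)
  u2 <- config$rho_ab * u1 + sqrt(1 - config$rho_ab^2) * stats::rnorm(ng)
  call_a <- matrix(0L, n, s)
  call_b <- matrix(0L, n, s)
  call_a[idx] <- as.integer(u1 <= stats::qnorm(p_a[gl_patient]))
  call_b[idx] <- as.integer(u2 <= stats::qnorm(p_b[gl_patient]))

  ## independent false positives at non-diseased sites
  neg <- which(truth == 0L)
  call_a[neg] <- stats::rbinom(length(neg), 1L, config$fp_a)
  call_b[neg] <- stats::rbinom(length(neg), 1L, config$fp_b)

  records <- data.frame(
    patient_id = rep(pid, each = s),
    site = rep(QUADRANT_SITES[seq_len(s)], times = n),
    truth = as.integer(t(truth)),
    call_a = as.integer(t(call_a)),
    call_b = as.integer(t(call_b)),
    stringsAsFactors = FALSE
  )
  as_cohort(records, level = "gland")
}

# fast path used by the Monte-Carlo drivers: same generative process, but
# returns per-cluster summary counts directly instead of a records frame
.simulate_summaries <- function(config) {
  n <- config$n_patients
  g <- 1L + stats::rbinom(n, 1L, config$p_two_glands)
  za <- stats::rnorm(n)
  zb <- config$rho_patient * za +
    sqrt(1 - config$rho_patient^2) * stats::rnorm(n)
  propensity <- function(z, mu) {
    if (config$icc == 0 || mu == 0 || mu == 1) return(rep(mu, n))
    sh <- .beta_shapes(mu, config$icc)
    stats::qbeta(stats::pnorm(z), sh["alpha"], sh["beta"])
  }
  p_a <- propensity(za, config$se_a)
  p_b <- propensity(zb, config$se_b)
  gl_patient <- rep(seq_len(n), times = g)
  ng <- length(gl_patient)
  u1 <- stats::rnorm(ng)
  u2 <- config$rho_ab * u1 + sqrt(1 - config$rho_ab^2) * stats::rnorm(ng)
  det_a <- as.integer(u1 <= stats::qnorm(p_a[gl_patient]))
  det_b <- as.integer(u2 <= stats::qnorm(p_b[gl_patient]))
  x_a <- as.integer(rowsum(det_a, gl_patient, reorder = TRUE))
  x_b <- as.integer(rowsum(det_b, gl_patient, reorder = TRUE))
  # per-gland discordances, kept so naive (unclustered) McNemar can be
  # computed on the same draws
  disc_b <- as.integer(rowsum(as.integer(det_a == 1L & det_b == 0L),
                              gl_patient, reorder = TRUE))
  disc_c <- as.integer(rowsum(as.integer(det_a == 0L & det_b == 1L),
                              gl_patient, reorder = TRUE))
  m <- config$sites_per_patient - g
  f_a <- stats::rbinom(n, m, config$fp_a)
  f_b <- stats::rbinom(n, m, config$fp_b)
  data.frame(patient_id = sprintf("P%04d", seq_len(n)), n_pos = g,
             x_a = x_a, x_b = x_b, m_neg = m, f_a = f_a, f_b = f_b,
             disc_b = disc_b, disc_c = disc_c,
             stringsAsFactors = FALSE)
}

#' Empirical moments of generated cohorts
#'
#' Parameter-recovery harness for [simulate_cohort()]: over replicate
#' cohorts it reports, with Monte-Carlo standard errors, the empirical
#' marginal sensitivities and false-positive rates, the intracluster
#' correlation of detections (pairwise product-moment estimator over
#' within-patient gland pairs), and the within-gland odds ratio of the two
#' tests' detections (Haldane-corrected).
#'
#' @param cohorts list of >= 100 cohorts from the same configuration.
#' @return data.frame of class `generator_moments` with columns `moment`,
#'   `test`, `mean`, `mc_se`, `n_reps`.
#' @export
estimate_generator_moments <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 100L) {
    stop("moment estimation needs >= 100 replicate cohorts")
  }
  per_rep <- lapply(cohorts, function(coh) {
    s <- if (inherits(coh, "cohort")) cluster_summaries(coh) else coh
    npos <- sum(s$n_pos); mneg <- sum(s$m_neg)
    pair_tot <- sum(choose(s$n_pos, 2))
    icc_of <- function(x) {
      p <- sum(x) / npos
      if (pair_tot == 0 || p <= 0 || p >= 1) return(NA_real_)
      m11 <- sum(choose(x, 2)) / pair_tot
      (m11 - p^2) / (p * (1 - p))
    }
    # within-gland 2x2 of the paired detections (needs gland records)
    cells <- if (inherits(coh, "cohort")) {
      pos <- coh[coh$truth == 1L, , drop = FALSE]
      c(n11 = sum(pos$call_a == 1 & pos$call_b == 1),
        n10 = sum(pos$call_a == 1 & pos$call_b == 0),
        n01 = sum(pos$call_a == 0 & pos$call_b == 1),
        n00 = sum(pos$call_a == 0 & pos$call_b == 0))
    } else c(n11 = NA, n10 = NA, n01 = NA, n00 = NA)
    c(se_a = sum(s$x_a) / npos, se_b = sum(s$x_b) / npos,
      fp_a = sum(s$f_a) / mneg, fp_b = sum(s$f_b) / mneg,
      icc_a = icc_of(s$x_a), icc_b = icc_of(s$x_b), cells)
  })
  m <- do.call(rbind, per_rep)
  summ <- function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), mc_se = stats::sd(v) / sqrt(length(v)),
      n_reps = length(v))
  }
  rows <- t(apply(m[, 1:6, drop = FALSE], 2, summ))
  # paired odds ratio from cells pooled over replicates: the per-replicate
  # Haldane-corrected ratio is badly biased when a cell's expectation is
  # below 1 (near-perfect tests); pooling removes that
  cells <- colSums(m[, c("n11", "n10", "n01", "n00"), drop = FALSE])
  if (anyNA(cells)) {
    log_or <- NA_real_; log_or_se <- NA_real_
  } else {
    if (any(cells == 0)) cells <- cells + 0.5
    log_or <- log(cells[["n11"]]) + log(cells[["n00"]]) -
      log(cells[["n10"]]) - log(cells[["n01"]])
    log_or_se <- sqrt(sum(1 / cells))
  }
  out <- data.frame(
    moment = c("sensitivity", "sensitivity", "fp_rate", "fp_rate",
               "icc", "icc", "log_odds_ratio"),
    test = c("A", "B", "A", "B", "A", "B", "AB"),
    mean = c(rows[, "mean"], log_or),
    mc_se = c(rows[, "mc_se"], log_or_se),
    n_reps = c(as.integer(rows[, "n_reps"]), nrow(m)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("generator_moments", "data.frame")
  out
}
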