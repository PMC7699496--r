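test_that("pooled sensitivity and specificity follow the 2x2 counts", {
  expect_equal(pooled_sensitivity(tvt_table(52, 1, 4, 3)), 52 / 53)
  expect_equal(pooled_sensitivity(tvt_table(53, 0, 6, 1)), 1)
  expect_equal(pooled_sensitivity(tvt_table(0, 5, 0, 0)), 0)
  expect_equal(pooled_specificity(tvt_table(52, 1, 4, 3)), 3 / 7)
  expect_error(pooled_sensitivity(tvt_table(0, 0, 2, 2)), "undefined")
  expect_error(pooled_specificity(tvt_table(2, 2, 0, 0)), "undefined")
})

test_that("Clopper-Pearson interval hits its closed-form boundary cases", {
  ci <- clopper_pearson_ci(0, 10)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 - 0.025^(1 / 10))
  ci_n <- clopper_pearson_ci(53, 53)
  expect_equal(ci_n$upper, 1)
  expect_equal(ci_n$lower, 0.025^(1 / 53))
  expect_equal(round_half_up(ci_n$lower, 2), 0.93)
  ci52 <- clopper_pearson_ci(52, 53)
  expect_equal(round_half_up(ci52$lower, 2), 0.90)
  expect_equal(round_half_up(ci52$upper, 2), 1.00)
  expect_error(clopper_pearson_ci(5, 4), "0 <= x <= n")
  expect_error(clopper_pearson_ci(2, 10, level = 1.2), "level")
})

test_that("Clopper-Pearson matches the exact binomial test inversion", {
  for (n in c(1, 2, 10, 53)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      ci <- clopper_pearson_ci(x, n)
      ref <- binom.test(x, n)$conf.int
      expect_equal(ci$lower, ref[1], tolerance = 1e-12)
      expect_equal(ci$upper, ref[2], tolerance = 1e-12)
    }
  }
})

test_that("Wilson score interval matches its formula and stays in [0,1]", {
  # frozen from a hand evaluation of the score formula at z = 1.959964
  w <- wilson_ci(52, 53)
  expect_equal(w$lower, 0.9010, tolerance = 1e-3)
  expect_equal(w$upper, 0.9972, tolerance = 1e-3)
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_equal(wilson_ci(10, 10)$upper, 1)
  # score interval shrinks toward 1/2 relative to the Wald interval
  w5 <- wilson_ci(5, 10)
  wald_half <- qnorm(0.975) * sqrt(0.5 * 0.5 / 10)
  expect_lt(w5$upper - w5$lower, 2 * wald_half)
  expect_equal((w5$upper + w5$lower) / 2, 0.5)  # symmetric center at p = 1/2
  # independent oracle: prop.test without continuity correction
  for (x in c(1, 5, 9)) {
    ref <- prop.test(x, 10, correct = FALSE)$conf.int
    w <- wilson_ci(x, 10)
    expect_equal(w$lower, ref[1], tolerance = 1e-10)
    expect_equal(w$upper, ref[2], tolerance = 1e-10)
  }
})

test_that("exact interval coverage is at least nominal", {
  set.seed(401)
  for (p in c(0.5, 0.8, 0.95)) {
    for (n in c(10, 53)) {
      x <- rbinom(10000, n, p)
      lower <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
      upper <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
      coverage <- mean(lower <= p & p <= upper)
      expect_gte(coverage, 0.95 - 0.015)
    }
  }
})

test_that("cluster-robust sensitivity reproduces the worked variance", {
  s <- make_cluster_summaries(n_pos = c(2, 2, 1), x_a = c(1, 2, 1),
                              x_b = c(1, 2, 1))
  est <- cluster_sensitivity(s, "A")
  expect_equal(est$estimate, 0.8)
  expect_equal(est$se^2, 0.0336)
  expect_equal(est$se, sqrt(0.0336), tolerance = 1e-12)
  expect_equal(est$n_clusters, 3L)
})

test_that("cluster-robust variance degenerates and reduces as expected", {
  # all clusters fully detected: no residuals
  s <- make_cluster_summaries(n_pos = c(2, 1, 3), x_a = c(2, 1, 3),
                              x_b = c(2, 1, 3))
  expect_equal(cluster_sensitivity(s, "A")$se, 0)
  expect_equal(cluster_sensitivity(s, "A")$estimate, 1)
  # all singleton clusters: small-sample-corrected binomial form
  x <- c(1, 1, 0, 1, 0, 1, 1, 1)
  s1 <- make_cluster_summaries(n_pos = 1, x_a = x, x_b = x)
  p <- mean(x)
  expect_equal(cluster_sensitivity(s1, "A")$se^2,
               p * (1 - p) / (length(x) - 1))
  expect_error(cluster_sensitivity(make_cluster_summaries(1, 1, 1), "A"),
               ">= 2 informative clusters")
})

test_that("ratio estimator ignores cluster ordering and uses totals only", {
  set.seed(77)
  n <- sample(1:3, 12, replace = TRUE)
  xa <- rbinom(12, n, 0.8)
  s <- make_cluster_summaries(n_pos = n, x_a = xa, x_b = xa)
  perm <- sample(12)
  sp <- make_cluster_summaries(n_pos = n[perm], x_a = xa[perm],
                               x_b = xa[perm])
  e1 <- cluster_sensitivity(s, "A"); e2 <- cluster_sensitivity(sp, "A")
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e1$se, e2$se)
  expect_equal(e1$estimate, sum(xa) / sum(n))
})

test_that("sandwich SE exceeds the naive binomial SE under clustering", {
  cfg <- sim_config(se_a = 0.8, se_b = 0.8, icc = 0.5, p_two_glands = 1)
  set.seed(88)
  wins <- 0; reps <- 100
  for (i in seq_len(reps)) {
    s <- clustsens:::.simulate_summaries(cfg)
    sand <- cluster_sensitivity(s, "A")
    naive <- sqrt(sand$estimate * (1 - sand$estimate) / sum(s$n_pos))
    wins <- wins + (sand$se > naive)
  }
  expect_gt(wins / reps, 0.9)
})

test_that("logit-scale interval keeps near-1 estimates inside [0,1]", {
  s <- make_cluster_summaries(n_pos = rep(2, 10),
                              x_a = c(rep(2, 9), 1), x_b = 2)
  ident <- cluster_sensitivity(s, "A", scale = "identity")
  logit <- cluster_sensitivity(s, "A", scale = "logit")
  expect_equal(ident$upper, 1)   # clamped
  expect_lt(logit$upper, 1)      # genuinely interior
  expect_equal(logit$estimate, ident$estimate)
  expect_true(logit$lower <= logit$estimate &&
                logit$estimate <= logit$upper)
})

test_that("cluster specificity mirrors the sensitivity estimator", {
  s <- make_cluster_summaries(n_pos = c(1, 1), x_a = c(1, 1), x_b = c(1, 1),
                              m_neg = c(3, 3), f_a = c(1, 0), f_b = c(0, 0))
  est <- cluster_specificity(s, "A")
  expect_equal(est$estimate, 5 / 6)
  expect_equal(cluster_specificity(s, "B")$estimate, 1)
})
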