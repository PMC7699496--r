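test_that("classical McNemar variants match enumeration and arithmetic", {
  sym <- mcnemar_test(agreement_table(4, 5, 5, 2), "chi2")
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # exact: two-sided binomial enumeration at p = 1/2
  ex <- mcnemar_test(agreement_table(0, 3, 0, 0), "exact")
  enum <- 2 * sum(dbinom(0:0, 3, 0.5))   # only c = 0 is as extreme
  expect_equal(ex$p_value, enum)
  expect_equal(ex$p_value, 0.25)

  chi <- mcnemar_test(agreement_table(0, 10, 2, 0), "chi2")
  expect_equal(chi$statistic, 64 / 12)
  expect_equal(chi$df, 1L)

  # oracle: stats::mcnemar.test on the same 2x2
  m <- matrix(c(7, 2, 10, 4), 2, 2)
  ref <- mcnemar.test(m, correct = FALSE)
  mine <- mcnemar_test(agreement_table(7, 10, 2, 4), "chi2")
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, unname(ref$p.value))
  ref_cc <- mcnemar.test(m, correct = TRUE)
  mine_cc <- mcnemar_test(agreement_table(7, 10, 2, 4), "chi2_cc")
  expect_equal(mine_cc$statistic, unname(ref_cc$statistic))
})

test_that("McNemar handles the no-discordance edge", {
  expect_warning(res <- mcnemar_test(agreement_table(5, 0, 0, 5), "exact"),
                 "no discordant")
  expect_equal(res$p_value, 1)
  expect_error(mcnemar_test(agreement_table(5, 0, 0, 5), "chi2"),
               "degenerate")
})

test_that("cluster-adjusted McNemar is null at identical detections", {
  s <- make_cluster_summaries(n_pos = c(2, 1, 2), x_a = c(1, 1, 2),
                              x_b = c(1, 1, 2))
  res <- cluster_mcnemar(s)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("cluster-adjusted McNemar agrees with a brute-force transcription", {
  # exhaustive over all 2-cluster states with up to 2 sites per cluster
  states <- expand.grid(n = 1:2, xa = 0:2, xb = 0:2)
  states <- states[states$xa <= states$n & states$xb <= states$n, ]
  for (i in seq_len(nrow(states))) {
    for (j in seq_len(nrow(states))) {
      n <- c(states$n[i], states$n[j])
      xa <- c(states$xa[i], states$xa[j])
      xb <- c(states$xb[i], states$xb[j])
      oracle <- brute_force_cluster_mcnemar(xa, xb, n)
      s <- make_cluster_summaries(n_pos = n, x_a = xa, x_b = xb)
      mine <- tryCatch(cluster_mcnemar(s), error = function(e) NULL)
      if (is.null(mine)) {
        # degenerate: zero variance with nonzero difference
        expect_true(!is.finite(oracle$statistic) || oracle$statistic == 0 ||
                      is.nan(oracle$statistic) ||
                      (oracle$p == 0 && is.infinite(oracle$statistic)))
      } else {
        expect_equal(mine$statistic, oracle$statistic, tolerance = 1e-12)
        expect_equal(mine$p_value, oracle$p, tolerance = 1e-12)
      }
    }
  }
})

test_that("adjusted statistic is invariant to relabeling and A/B swap", {
  set.seed(12)
  for (r in 1:20) {
    k <- sample(3:8, 1)
    n <- sample(1:3, k, replace = TRUE)
    xa <- rbinom(k, n, 0.8); xb <- rbinom(k, n, 0.8)
    s <- make_cluster_summaries(n_pos = n, x_a = xa, x_b = xb)
    perm <- sample(k)
    sp <- make_cluster_summaries(n_pos = n[perm], x_a = xa[perm],
                                 x_b = xb[perm])
    sw <- make_cluster_summaries(n_pos = n, x_a = xb, x_b = xa)
    base <- tryCatch(cluster_mcnemar(s), error = function(e) NULL)
    if (is.null(base)) next
    expect_equal(cluster_mcnemar(sp)$statistic, base$statistic)
    expect_equal(cluster_mcnemar(sw)$statistic, base$statistic)
  }
})

test_that("with singleton clusters and b = c the adjusted statistic is zero", {
  s <- make_cluster_summaries(n_pos = 1, x_a = c(1, 0, 1, 0, 1),
                              x_b = c(0, 1, 0, 1, 1))
  expect_equal(cluster_mcnemar(s)$statistic, 0)
  expect_equal(cluster_mcnemar(s)$p_value, 1)
})
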