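test_that("cohort CSV round-trips through write and read", {
  coh <- fixture_cohort()
  expect_s3_class(coh, "cohort")
  expect_identical(cohort_level(coh), "gland")
  expect_equal(nrow(coh), 240L)
  expect_equal(length(unique(coh$patient_id)), 60L)
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- suppressWarnings(read_cohort(path))
  expect_identical(as.data.frame(coh), as.data.frame(back))
})

test_that("reader coerces dialect vocabularies and flags bad values", {
  path <- write_cohort_csv(c(
    "patient_id,site,truth,call_a,call_b",
    "P01,right-upper,yes,Pos,1",
    "P01,right-lower,no,NEG,0"
  ))
  coh <- suppressWarnings(read_cohort(path))
  expect_equal(coh$truth, c(1L, 0L))
  expect_equal(coh$call_a, c(1L, 0L))

  bad <- write_cohort_csv(c(
    "patient_id,site,truth,call_a,call_b",
    "P01,right-upper,1,0,0",
    "P01,right-lower,maybe,0,0"
  ))
  expect_error(read_cohort(bad), "maybe")
  expect_error(read_cohort(bad), "line 3")
})

test_that("validation rejects duplicates, bad sites and missing columns", {
  dup <- write_cohort_csv(c(
    "patient_id,site,truth,call_a,call_b",
    "P01,right-upper,1,1,1",
    "P01,right-upper,0,0,0"
  ))
  expect_error(read_cohort(dup), "duplicate")
  expect_error(
    as_cohort(data.frame(patient_id = "P01", site = "mediastinum",
                         truth = 1, call_a = 0, call_b = 0)),
    "site label")
  expect_error(read_cohort(write_cohort_csv("patient_id,site,truth")),
               "lacks column")
  expect_error(
    as_cohort(data.frame(patient_id = "P01", site = "right-upper",
                         truth = NA, call_a = 0, call_b = 0)),
    "binary")
  # ectopic sites may repeat with ordinal suffixes
  eco <- as_cohort(data.frame(
    patient_id = "P01", site = c("right-upper", "ectopic", "ectopic-2"),
    truth = c(1, 1, 0), call_a = c(1, 0, 0), call_b = c(1, 1, 0)))
  expect_equal(nrow(eco), 3L)
})

test_that("surgery-negative clusters warn but are admitted", {
  expect_warning(
    as_cohort(data.frame(patient_id = c("P01", "P02"),
                         site = "right-upper",
                         truth = c(1, 0), call_a = c(1, 0),
                         call_b = c(1, 0))),
    "surgery-negative")
})

test_that("patient-level aggregation applies the positivity rules", {
  # two true glands, A positive at exactly one of them
  coh <- mini_cohort(cbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(1, 1, 0, 0)))
  pat <- aggregate_patient_level(coh, "location_match")
  expect_identical(cohort_level(pat), "patient")
  expect_equal(pat$truth, 1L)
  expect_equal(pat$call_a, 1L)

  # one true gland, A positive only at a non-diseased site
  coh2 <- mini_cohort(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 0)))
  expect_equal(aggregate_patient_level(coh2, "location_match")$call_a, 0L)
  expect_equal(aggregate_patient_level(coh2, "any_call")$call_a, 1L)

  # all-negative patient with no calls
  coh3 <- mini_cohort(cbind(c(0, 0), c(0, 0), c(0, 0)))
  pat3 <- suppressWarnings(aggregate_patient_level(coh3))
  expect_equal(unlist(pat3[, c("truth", "call_a", "call_b")],
                      use.names = FALSE), c(0L, 0L, 0L))

  expect_error(aggregate_patient_level(pat), "already at patient level")
  # one row per distinct input patient
  pat_fix <- suppressWarnings(aggregate_patient_level(fixture_cohort()))
  expect_equal(sort(unique(pat_fix$patient_id)),
               sort(unique(fixture_cohort()$patient_id)))
  expect_equal(nrow(pat_fix), 60L)
})

test_that("test-vs-truth tables partition the records", {
  coh <- fixture_cohort()
  for (tt in c("A", "B")) {
    tab <- test_vs_truth(coh, tt)
    expect_equal(tab$tp + tab$fn + tab$fp + tab$tn, nrow(coh))
    ref <- gland_level_tables()[[tt]]
    expect_equal(tab[c("tp", "fn", "fp", "tn")],
                 ref[c("tp", "fn", "fp", "tn")])
  }
  empty <- as_cohort(data.frame(patient_id = character(), site = character(),
                                truth = integer(), call_a = integer(),
                                call_b = integer()))
  tab0 <- test_vs_truth(empty, "A")
  expect_equal(unlist(tab0[c("tp", "fn", "fp", "tn")], use.names = FALSE),
               rep(0L, 4))
})

test_that("cluster summaries count sites, detections and false calls", {
  coh <- mini_cohort(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 1, 0, 1)))
  s <- cluster_summaries(coh)
  expect_equal(s$n_pos, 2L)
  expect_equal(s$x_a, 2L)
  expect_equal(s$x_b, 1L)
  expect_equal(s$m_neg, 2L)
  expect_equal(s$f_a, 0L)
  expect_equal(s$f_b, 1L)

  sf <- cluster_summaries(fixture_cohort())
  expect_equal(sum(sf$n_pos), 75L)
  expect_equal(sum(sf$m_neg), 165L)
  expect_equal(sum(sf$n_pos) + sum(sf$m_neg), 240L)
  # detection totals tie out against the 2x2 tables
  expect_equal(sum(sf$x_a), test_vs_truth(fixture_cohort(), "A")$tp)
  expect_equal(sum(sf$x_b), test_vs_truth(fixture_cohort(), "B")$tp)
})

test_that("method agreement counts paired calls", {
  coh <- mini_cohort(cbind(c(1, 1, 0, 0), c(1, 1, 0, 1), c(1, 0, 1, 0)))
  all_sites <- method_agreement(coh)
  expect_equal(unlist(all_sites[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 2L, 1L, 0L))
  pos_only <- method_agreement(coh, truth_positive_only = TRUE)
  expect_equal(unlist(pos_only[c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 1L, 0L, 0L))
})
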