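#' Published patient-level 2x2 tables
#'
#' The marginal patient-level test-vs-surgery tables of the 60-patient
#' localization trial the package's defaults mirror: test A (dual-isotope
#' subtraction SPECT) with tp=52, fn=1, fp=4, tn=3 and test B (choline PET)
#' with tp=53, fn=0, fp=6, tn=1. Read from the packaged CSV fixture.
#'
#' @return named list of two [tvt_table()] objects, `A` and `B`.
#' @export
patient_level_tables <- function() {
  path <- system.file("extdata", "patient_level_tables.csv",
                      package = "clustsens", mustWork = TRUE)
  .read_tables(path, level = "patient")
}

#' Published gland-level 2x2 tables
#'
#' Gland-level marginals over 240 sites (75 surgery-positive, 165
#' surgery-negative): test A tp=59, fn=16, fp=4, tn=161; test B tp=60,
#' fn=15, fp=4, tn=161.
#'
#' @return named list of two [tvt_table()] objects, `A` and `B`.
#' @export
gland_level_tables <- function() {
  path <- system.file("extdata", "gland_level_tables.csv",
                      package = "clustsens", mustWork = TRUE)
  .read_tables(path, level = "gland")
}

.read_tables <- function(path, level) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i) {
    tvt_table(tp = d$tp[i], fn = d$fn[i], fp = d$fp[i], tn = d$tn[i],
              level = level, test = d$test[i])
  })
  names(out) <- d$test
  out
}

#' Synthetic gland-level cohort matching the published marginals
#'
#' Builds, deterministically and without randomness, a 240-record
#' gland-level cohort (60 patients x 4 quadrant sites) whose test-vs-surgery
#' tables equal the published gland-level marginals: 75 surgery-positive
#' sites, test A detecting 59 with 4 false calls, test B detecting 60 with
#' 4 false calls. The published tables determine only these margins, not the
#' per-patient arrangement, so the within-patient layout here is a synthetic
#' convention: 22 patients carry two diseased glands and 31 one (the
#' patient-level and gland-level tables of the source trial are mutually
#' inconsistent, so no cohort can reproduce both; this one reproduces the
#' gland level). Seven patients are surgery-negative and carry the false
#' calls, which triggers the usual surgery-negative warning.
#'
#' @return A gland-level `cohort`.
#' @export
synthetic_gland_cohort <- function() {
  n <- 60L
  pid <- sprintf("P%02d", seq_len(n))
  truth <- call_a <- call_b <- matrix(0L, n, 4,
                                      dimnames = list(NULL, QUADRANT_SITES))
  truth[1:53, "right-upper"] <- 1L
  truth[1:22, "left-upper"] <- 1L        # 53 + 22 = 75 diseased sites
  call_a[1:53, "right-upper"] <- 1L
  call_a[1:22, "left-upper"] <- 1L
  call_a[1:16, "left-upper"] <- 0L       # 16 misses -> 59 detections
  call_b[1:53, "right-upper"] <- 1L
  call_b[1:22, "left-upper"] <- 1L
  call_b[1:15, "left-upper"] <- 0L       # 15 misses -> 60 detections
  call_a[54:57, "right-lower"] <- 1L     # 4 false calls each test
  call_b[57:60, "right-lower"] <- 1L
  records <- data.frame(
    patient_id = rep(pid, each = 4),
    site = rep(QUADRANT_SITES, times = n),
    truth = as.integer(t(truth)),
    call_a = as.integer(t(call_a)),
    call_b = as.integer(t(call_b)),
    stringsAsFactors = FALSE
  )
  as_cohort(records, level = "gland")
}
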