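# Small in-code cohort builders shared across the suite.

# one patient per row of (truth, call_a, call_b) site triples
mini_cohort <- function(..., level = "gland") {
  patients <- list(...)
  rows <- lapply(seq_along(patients), function(i) {
    m <- patients[[i]]
    data.frame(patient_id = sprintf("P%02d", i),
               site = QUADRANT_SITES[seq_len(nrow(m))],
               truth = m[, 1], call_a = m[, 2], call_b = m[, 3],
               stringsAsFactors = FALSE)
  })
  suppressWarnings(as_cohort(do.call(rbind, rows), level = level))
}

write_cohort_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

fixture_cohort <- function() {
  suppressWarnings(read_cohort(
    system.file("extdata", "gland_cohort_synthetic.csv",
                package = "clustsens", mustWork = TRUE)))
}

# direct transcription of the sandwich formula, kept deliberately loop-based
# and separate from the package implementation
brute_force_cluster_mcnemar <- function(x_a, x_b, n) {
  keep <- n > 0
  x_a <- x_a[keep]; x_b <- x_b[keep]; n <- n[keep]
  k <- length(n)
  d <- (sum(x_a) - sum(x_b)) / sum(n)
  v <- 0
  for (i in seq_len(k)) v <- v + ((x_a[i] - x_b[i]) - d * n[i])^2
  v <- v * k / (k - 1) / sum(n)^2
  if (v == 0 && d == 0) return(list(statistic = 0, p = 1))
  stat <- d^2 / v
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}
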