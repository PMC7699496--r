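#' Full clustered paired-accuracy analysis of a cohort
#'
#' Runs the complete pipeline on a gland-level cohort: aggregation to
#' patient level, 2x2 tables for both tests at both grains, pooled
#' sensitivities with exact (Clopper-Pearson) intervals at the patient
#' level, cluster-robust (sandwich) sensitivity and specificity estimates at
#' the gland level, the cluster-adjusted McNemar comparison of the two
#' tests, and the non-inferiority test for the sensitivity difference. Both
#' grains are always reported; sensitivity is the lead effect measure (in a
#' trial where every patient is expected to carry disease, patient-level
#' specificity is nearly vacuous), with specificities and agreement counts
#' kept in the serialized object.
#'
#' Stages that cannot run on degenerate inputs (e.g. a single patient)
#' surface their error message in the corresponding slot instead of
#' aborting the report.
#'
#' @param cohort a gland-level `cohort`, or a path to a cohort CSV.
#' @param rule patient-level positivity rule, see
#'   [aggregate_patient_level()].
#' @param delta non-inferiority margin (default -0.10).
#' @param alpha one-sided level of the non-inferiority test (default 0.05,
#'   companion CI level `1 - 2*alpha` = 0.90).
#' @param conf_level level of the per-test confidence intervals
#'   (default 0.95).
#' @param mcnemar_variant variant of the classical (unclustered) McNemar
#'   test computed on the patient-level agreement table, see
#'   [mcnemar_test()].
#' @param dialect [cohort_dialect()] used when `cohort` is a file path.
#' @return An `analysis_report` list; print it for a human-readable layout
#'   or serialize with [report_to_json()].
#' @export
analyze_cohort <- function(cohort, rule = c("location_match", "any_call"),
                           delta = -0.10, alpha = 0.05, conf_level = 0.95,
                           mcnemar_variant = c("exact", "chi2", "chi2_cc"),
                           dialect = cohort_dialect()) {
  rule <- match.arg(rule)
  mcnemar_variant <- match.arg(mcnemar_variant)
  notes <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  input_digest <- NULL
  if (is.character(cohort)) {
    input_digest <- unname(tools::md5sum(cohort))
    cohort <- collect(read_cohort(cohort, dialect = dialect))
  }
  stopifnot(inherits(cohort, "cohort"))
  if (cohort_level(cohort) != "gland") {
    stop("analyze_cohort expects a gland-level cohort")
  }
  try_stage <- function(stage, expr) {
    tryCatch(collect(expr), error = function(e) {
      notes <<- c(notes, paste0(stage, ": ", conditionMessage(e)))
      list(error = conditionMessage(e), stage = stage)
    })
  }
  patient <- collect(aggregate_patient_level(cohort, rule = rule))
  summaries <- cluster_summaries(cohort)

  tables <- list(
    patient = list(A = test_vs_truth(patient, "A"),
                   B = test_vs_truth(patient, "B")),
    gland = list(A = test_vs_truth(cohort, "A"),
                 B = test_vs_truth(cohort, "B"))
  )
  patient_sens <- lapply(tables$patient, function(tab) {
    try_stage("patient sensitivity", {
      clopper_pearson_ci(tab$tp, tab$tp + tab$fn, level = conf_level)
    })
  })
  gland_sens <- lapply(c(A = "A", B = "B"), function(tt) {
    try_stage("gland sensitivity",
              cluster_sensitivity(summaries, tt, level = conf_level))
  })
  gland_spec <- lapply(c(A = "A", B = "B"), function(tt) {
    try_stage("gland specificity",
              cluster_specificity(summaries, tt, level = conf_level))
  })
  agreement <- list(
    patient = method_agreement(patient),
    gland_truth_positive = method_agreement(cohort, truth_positive_only = TRUE)
  )
  comparison <- try_stage("cluster-adjusted McNemar",
                          cluster_mcnemar(summaries))
  patient_mcnemar <- try_stage("patient-level McNemar",
                               mcnemar_test(agreement$patient,
                                            variant = mcnemar_variant))
  ni <- try_stage("non-inferiority",
                  noninferiority_test(summaries, delta = delta,
                                      alpha = alpha))
  structure(list(
    tables = tables,
    patient_sensitivity = patient_sens,
    gland_sensitivity = gland_sens,
    gland_specificity = gland_spec,
    agreement = agreement,
    comparison = comparison,
    patient_mcnemar = patient_mcnemar,
    noninferiority = ni,
    notes = notes,
    provenance = list(
      package = "clustsens",
      version = as.character(utils::packageVersion("clustsens")),
      input_md5 = input_digest,
      rule = rule, delta = delta, alpha = alpha,
      conf_level = conf_level,
      n_patients = length(unique(cohort$patient_id)),
      n_records = nrow(cohort)
    )
  ), class = "analysis_report")
}

.fmt_stage <- function(x, fmt) {
  if (!is.null(x$error)) paste0("unavailable (", x$error, ")") else fmt(x)
}

#' @export
print.analysis_report <- function(x, ...) {
  fmt_ci <- function(e) sprintf("%.2f (%d%% CI: %.2f-%.2f)",
                                round_half_up(e$estimate, 2),
                                round(100 * e$level),
                                round_half_up(e$lower, 2),
                                round_half_up(e$upper, 2))
  cat("Clustered paired diagnostic accuracy report\n")
  cat(sprintf("  %d patients, %d gland records\n",
              x$provenance$n_patients, x$provenance$n_records))
  cat("\nPatient level (exact intervals)\n")
  for (tt in c("A", "B")) {
    tab <- x$tables$patient[[tt]]
    cat(sprintf("  Test %s: tp=%d fn=%d fp=%d tn=%d; sensitivity %s\n",
                tt, tab$tp, tab$fn, tab$fp, tab$tn,
                .fmt_stage(x$patient_sensitivity[[tt]], fmt_ci)))
  }
  cat("\nGland level (cluster-robust sandwich intervals)\n")
  for (tt in c("A", "B")) {
    tab <- x$tables$gland[[tt]]
    cat(sprintf("  Test %s: tp=%d fn=%d fp=%d tn=%d; sensitivity %s\n",
                tt, tab$tp, tab$fn, tab$fp, tab$tn,
                .fmt_stage(x$gland_sensitivity[[tt]], fmt_ci)))
  }
  cat("\nMethod comparison (cluster-adjusted McNemar)\n  ")
  if (!is.null(x$comparison$error)) {
    cat("unavailable (", x$comparison$error, ")\n", sep = "")
  } else {
    print(x$comparison)
  }
  cat("\nNon-inferiority\n")
  if (!is.null(x$noninferiority$error)) {
    cat("  unavailable (", x$noninferiority$error, ")\n", sep = "")
  } else {
    print(x$noninferiority)
  }
  if (length(x$notes)) {
    cat("\nNotes\n")
    for (nt in unique(x$notes)) cat("  - ", nt, "\n", sep = "")
  }
  invisible(x)
}

#' Serialize an analysis report (or any result object) to JSON
#'
#' Strips classes down to plain lists and writes JSON with unboxed scalars,
#' so the file round-trips losslessly through [jsonlite::read_json()].
#'
#' @param x an `analysis_report` or any of the package's result objects.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(x, path = NULL) {
  strip <- function(obj) {
    if (is.list(obj)) {
      lapply(unclass(obj), strip)
    } else obj
  }
  js <- jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
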