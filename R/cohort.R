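#' Standard gland-site labels
#'
#' The four thyroid-bed quadrants scored in a parathyroid localization study.
#' Ectopic glands carry the label `"ectopic"`, optionally with an ordinal
#' suffix (`"ectopic-2"`) when a patient has more than one.
#'
#' @export
QUADRANT_SITES <- c("right-upper", "right-lower", "left-upper", "left-lower")

.is_valid_site <- function(site) {
  site %in% QUADRANT_SITES | grepl("^ectopic(-[0-9]+)?$", site)
}

#' Column-name and value mapping for cohort files
#'
#' Declares how the columns of a CSV cohort file map onto the canonical
#' fields, and which strings count as positive/negative for the three binary
#' status columns. All tabular I/O is driven by such a mapping; columns are
#' matched by name, never by position.
#'
#' @param patient_id,site,truth,call_a,call_b column names in the file.
#' @param true_values,false_values case-insensitive strings accepted as
#'   positive / negative codes (in addition to `1`/`0`).
#' @return An object of class `cohort_dialect`.
#' @export
cohort_dialect <- function(patient_id = "patient_id", site = "site",
                           truth = "truth", call_a = "call_a",
                           call_b = "call_b",
                           true_values = c("1", "yes", "pos", "true", "+"),
                           false_values = c("0", "no", "neg", "false", "-")) {
  structure(list(patient_id = patient_id, site = site, truth = truth,
                 call_a = call_a, call_b = call_b,
                 true_values = tolower(true_values),
                 false_values = tolower(false_values)),
            class = "cohort_dialect")
}

#' Construct and validate a cohort of site records
#'
#' A cohort is the unit of every analysis in this package: a set of binary
#' site records (reference/surgical status plus the two tests' calls) grouped
#' into patient clusters. Validation enforces strictly binary status fields,
#' uniqueness of (patient, site), and recognised site labels. Surgery-negative
#' patients (no truth-positive site) are admitted with a warning: a
#' localization trial enrols on confirmed disease, so their presence usually
#' signals an upstream issue, yet published patient-level tables do contain
#' them.
#'
#' @param records data.frame with columns `patient_id`, `site`, `truth`,
#'   `call_a`, `call_b`; the three status columns must be 0/1 (or logical).
#' @param level analysis grain of the records, `"gland"` or `"patient"`.
#' @return A `cohort` object (a validated data.frame with a `level`
#'   attribute).
#' @export
as_cohort <- function(records, level = c("gland", "patient")) {
  level <- match.arg(level)
  required <- c("patient_id", "site", "truth", "call_a", "call_b")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("cohort records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$patient_id <- as.character(records$patient_id)
  records$site <- as.character(records$site)

  for (col in c("truth", "call_a", "call_b")) {
    v <- records[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (!is.numeric(v) || anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("column '", col, "' must be strictly binary (0/1) with no missing values")
    }
    records[[col]] <- as.integer(v)
  }
  if (anyNA(records$patient_id) || anyNA(records$site)) {
    stop("patient_id and site must not be missing")
  }
  bad_site <- !.is_valid_site(records$site)
  if (any(bad_site)) {
    stop("unrecognised site label(s): ",
         paste(unique(records$site[bad_site]), collapse = ", "),
         " (expected quadrants ", paste(QUADRANT_SITES, collapse = "/"),
         " or ectopic[-k])")
  }
  key <- paste(records$patient_id, records$site, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (patient, site) record(s): ",
         paste(unique(paste0(dup$patient_id, "/", dup$site)), collapse = ", "))
  }
  n_pos <- tapply(records$truth, records$patient_id, sum)
  n_neg_patients <- sum(n_pos == 0L)
  if (n_neg_patients > 0L) {
    warning(n_neg_patients,
            " patient(s) have no surgery-positive site (surgery-negative clusters)")
  }
  rownames(records) <- NULL
  structure(records, level = level, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records, %d patients, level = %s\n",
              nrow(x), length(unique(x$patient_id)), cohort_level(x)))
  NextMethod()
}

#' Analysis grain of a cohort
#' @param cohort a `cohort` object.
#' @return `"gland"` or `"patient"`.
#' @export
cohort_level <- function(cohort) attr(cohort, "level")

#' Read a cohort from a CSV file
#'
#' Reads long-format records (one row per patient-site) and validates them
#' into a [as_cohort()] cohort. Binary columns are coerced through the
#' dialect's positive/negative vocabularies; a value outside them is a parse
#' error naming the offending file line.
#'
#' @param path CSV file (RFC-4180, UTF-8, header row).
#' @param dialect a [cohort_dialect()] mapping file columns to fields.
#' @param level analysis grain recorded on the result.
#' @return A `cohort`.
#' @export
read_cohort <- function(path, dialect = cohort_dialect(),
                        level = c("gland", "patient")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  needed <- unlist(dialect[c("patient_id", "site", "truth", "call_a", "call_b")])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  coerce_binary <- function(values, col) {
    v <- tolower(trimws(values))
    out <- rep(NA_integer_, length(v))
    out[v %in% dialect$true_values] <- 1L
    out[v %in% dialect$false_values] <- 0L
    bad <- which(is.na(out))
    if (length(bad) > 0L) {
      # +1 for the header row so the number matches the file line
      stop("cannot parse '", values[bad[1L]], "' in column '", col,
           "' as binary (file line ", bad[1L] + 1L, ")")
    }
    out
  }
  records <- data.frame(
    patient_id = trimws(raw[[dialect$patient_id]]),
    site = trimws(raw[[dialect$site]]),
    truth = coerce_binary(raw[[dialect$truth]], dialect$truth),
    call_a = coerce_binary(raw[[dialect$call_a]], dialect$call_a),
    call_b = coerce_binary(raw[[dialect$call_b]], dialect$call_b),
    stringsAsFactors = FALSE
  )
  as_cohort(records, level = level)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] for the default dialect: the written file reads
#' back to an identical cohort.
#'
#' @param cohort a `cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse a gland-level cohort to one record per patient
#'
#' Patient truth is positive when any site is surgery-positive. Test
#' positivity follows `rule`:
#' \describe{
#'   \item{`location_match`}{a test is patient-positive only if it is positive
#'     at at least one truth-positive site — i.e. it must localize correctly.
#'     For surgery-negative patients (no truth-positive site) the test is
#'     positive if it calls any site, since no localization can be correct.}
#'   \item{`any_call`}{a test is patient-positive if it is positive at any
#'     site, regardless of whether that site harbours disease.}
#' }
#' `location_match` is the default: localization studies score the
#' preoperative call against the surgical site, not mere detection of
#' "something somewhere".
#'
#' @param cohort a gland-level `cohort`.
#' @param rule patient-positivity rule, see Details.
#' @return A patient-level `cohort` with one record per patient. The site
#'   column is meaningless at this grain and holds a fixed placeholder.
#' @export
aggregate_patient_level <- function(cohort,
                                    rule = c("location_match", "any_call")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "cohort"))
  if (cohort_level(cohort) != "gland") {
    stop("cohort is already at patient level; aggregation needs gland-level records")
  }
  ids <- unique(cohort$patient_id)
  agg <- function(pid) {
    rec <- cohort[cohort$patient_id == pid, , drop = FALSE]
    truth <- as.integer(any(rec$truth == 1L))
    call_at <- function(calls) {
      if (rule == "any_call" || truth == 0L) {
        as.integer(any(calls == 1L))
      } else {
        as.integer(any(calls == 1L & rec$truth == 1L))
      }
    }
    c(truth = truth, call_a = call_at(rec$call_a), call_b = call_at(rec$call_b))
  }
  m <- t(vapply(ids, agg, c(truth = 0L, call_a = 0L, call_b = 0L)))
  out <- data.frame(patient_id = ids, site = "right-upper",
                    truth = m[, "truth"], call_a = m[, "call_a"],
                    call_b = m[, "call_b"], stringsAsFactors = FALSE)
  # the site column is meaningless at patient grain; keep a fixed quadrant
  # label so the record passes the shared validator
  suppressWarnings(coh <- as_cohort(out, level = "patient"))
  n_neg <- sum(m[, "truth"] == 0L)
  if (n_neg > 0L) {
    warning(n_neg, " patient(s) have no surgery-positive site (surgery-negative clusters)")
  }
  coh
}

#' 2x2 table of one test against the reference standard
#'
#' Cross-classifies every record of the cohort by the chosen test's call and
#' the surgical truth, in the TP/FN/FP/TN layout of a diagnostic accuracy
#' table.
#'
#' @param cohort a `cohort` at either grain.
#' @param test `"A"` or `"B"`.
#' @return A `tvt_table` with fields `tp`, `fn`, `fp`, `tn`.
#' @export
test_vs_truth <- function(cohort, test = c("A", "B")) {
  test <- match.arg(test)
  stopifnot(inherits(cohort, "cohort"))
  call <- if (test == "A") cohort$call_a else cohort$call_b
  tvt_table(tp = sum(cohort$truth == 1L & call == 1L),
            fn = sum(cohort$truth == 1L & call == 0L),
            fp = sum(cohort$truth == 0L & call == 1L),
            tn = sum(cohort$truth == 0L & call == 0L),
            level = cohort_level(cohort), test = test)
}

#' Construct a test-vs-truth 2x2 count table
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @param level,test optional provenance tags.
#' @return A `tvt_table`.
#' @export
tvt_table <- function(tp, fn, fp, tn, level = NULL, test = NULL) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("tp, fn, fp, tn must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 level = level, test = test),
            class = "tvt_table")
}

#' @export
print.tvt_table <- function(x, ...) {
  cat("<test vs truth>",
      if (!is.null(x$test)) paste0(" test ", x$test) else "",
      if (!is.null(x$level)) paste0(" (", x$level, " level)") else "", "\n",
      sep = "")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("+", "-"), truth = c("+", "-")))
  print(m)
  invisible(x)
}

#' Paired agreement table of the two tests
#'
#' Cross-classifies each record by the two tests' calls: `a` both positive,
#' `b` A-positive/B-negative, `c` A-negative/B-positive, `d` both negative.
#' This is the table the classical McNemar test operates on.
#'
#' @param cohort a `cohort`; with `truth_positive_only = TRUE` only
#'   surgery-positive records enter, so discordances reflect detection, not
#'   false calls.
#' @param truth_positive_only restrict to truth-positive records.
#' @return A `method_agreement` object with fields `a`, `b`, `c`, `d`.
#' @export
method_agreement <- function(cohort, truth_positive_only = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rec <- if (truth_positive_only) cohort[cohort$truth == 1L, , drop = FALSE] else cohort
  agreement_table(a = sum(rec$call_a == 1L & rec$call_b == 1L),
                  b = sum(rec$call_a == 1L & rec$call_b == 0L),
                  c = sum(rec$call_a == 0L & rec$call_b == 1L),
                  d = sum(rec$call_a == 0L & rec$call_b == 0L))
}

#' Construct a paired 2x2 agreement table
#' @param a,b,c,d non-negative integer counts (b and c are the discordant
#'   cells).
#' @return A `method_agreement` object.
#' @export
agreement_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("a, b, c, d must be non-negative integers")
  }
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "method_agreement")
}

#' Per-patient cluster summaries
#'
#' Reduces a cohort to the per-cluster counts that drive every clustered
#' inference in the package: diseased sites (`n_pos`), detections by each
#' test among them (`x_a`, `x_b`), non-diseased sites (`m_neg`) and
#' false-positive calls (`f_a`, `f_b`).
#'
#' @param cohort a `cohort`.
#' @return data.frame of class `cluster_summaries`, one row per patient.
#' @export
cluster_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  pid <- factor(cohort$patient_id, levels = unique(cohort$patient_id))
  pos <- cohort$truth == 1L
  s <- data.frame(
    patient_id = levels(pid),
    n_pos = as.integer(tapply(pos, pid, sum)),
    x_a = as.integer(tapply(cohort$call_a == 1L & pos, pid, sum)),
    x_b = as.integer(tapply(cohort$call_b == 1L & pos, pid, sum)),
    m_neg = as.integer(tapply(!pos, pid, sum)),
    f_a = as.integer(tapply(cohort$call_a == 1L & !pos, pid, sum)),
    f_b = as.integer(tapply(cohort$call_b == 1L & !pos, pid, sum)),
    stringsAsFactors = FALSE
  )
  rownames(s) <- NULL
  class(s) <- c("cluster_summaries", "data.frame")
  s
}

#' Assemble cluster summaries from raw counts
#'
#' Convenience constructor (and validator) for hand-built or simulated
#' per-cluster counts, accepting vectors recycled to a common length.
#'
#' @param n_pos,x_a,x_b integer vectors; detections must satisfy
#'   `0 <= x <= n_pos`.
#' @param m_neg,f_a,f_b negative-site counts and false calls, defaulting to
#'   zero.
#' @param patient_id optional identifiers.
#' @return A `cluster_summaries` data.frame.
#' @export
make_cluster_summaries <- function(n_pos, x_a, x_b, m_neg = 0, f_a = 0,
                                   f_b = 0, patient_id = NULL) {
  k <- max(length(n_pos), length(x_a), length(x_b), length(m_neg))
  s <- data.frame(
    patient_id = if (is.null(patient_id)) sprintf("C%03d", seq_len(k)) else patient_id,
    n_pos = as.integer(rep_len(n_pos, k)),
    x_a = as.integer(rep_len(x_a, k)),
    x_b = as.integer(rep_len(x_b, k)),
    m_neg = as.integer(rep_len(m_neg, k)),
    f_a = as.integer(rep_len(f_a, k)),
    f_b = as.integer(rep_len(f_b, k)),
    stringsAsFactors = FALSE
  )
  with(s, {
    if (any(n_pos < 0 | m_neg < 0)) stop("site counts must be non-negative")
    if (any(x_a < 0 | x_a > n_pos | x_b < 0 | x_b > n_pos)) {
      stop("detections x must satisfy 0 <= x <= n_pos")
    }
    if (any(f_a < 0 | f_a > m_neg | f_b < 0 | f_b > m_neg)) {
      stop("false calls f must satisfy 0 <= f <= m_neg")
    }
  })
  class(s) <- c("cluster_summaries", "data.frame")
  s
}
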