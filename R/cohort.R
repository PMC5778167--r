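#' Construct a lesion cohort
#'
#' The canonical container for a study arm: a long-format table of
#' target-lesion measurements (one row per patient, lesion and visit day)
#' plus the scheduled imaging days. Day 0 is treatment start; diameters are
#' longest diameters in mm. Validation enforces non-negative diameters and
#' days, uniqueness of (patient, lesion, day), and that every measurement
#' falls on a scheduled visit day — measurements at unscheduled days are
#' rejected rather than snapped, so switch-point candidates stay well
#' defined.
#'
#' @param measurements data.frame with columns `patient_id`, `lesion_id`,
#'   `day`, `diameter_mm`.
#' @param visit_days Strictly increasing integer vector of scheduled imaging
#'   days, starting at 0. Defaults to the days present in `measurements`
#'   (which must then include 0).
#' @param arm_label Free-text label for the arm.
#' @return An object of class `lesion_cohort`: a list with elements
#'   `measurements`, `visit_days`, `arm_label`.
#' @export
#' @examples
#' m <- data.frame(patient_id = "p1", lesion_id = c("l1", "l1"),
#'                 day = c(0L, 42L), diameter_mm = c(20, 14))
#' lesion_cohort(m, visit_days = c(0, 42), arm_label = "example")
lesion_cohort <- function(measurements, visit_days = NULL, arm_label = "") {
  req <- c("patient_id", "lesion_id", "day", "diameter_mm")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop("measurements lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- data.frame(
    patient_id = as.character(measurements$patient_id),
    lesion_id = as.character(measurements$lesion_id),
    day = as.integer(measurements$day),
    diameter_mm = as.numeric(measurements$diameter_mm),
    stringsAsFactors = FALSE
  )
  if (is.null(visit_days)) visit_days <- sort(unique(m$day))
  visit_days <- as.integer(visit_days)

  bad <- which(!is.finite(m$diameter_mm) | m$diameter_mm < 0)
  if (length(bad))
    stop("negative or non-finite diameter_mm at row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(is.na(m$day) | m$day < 0)
  if (length(bad))
    stop("negative or missing day at row(s): ", paste(bad, collapse = ", "))
  key <- paste(m$patient_id, m$lesion_id, m$day, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (patient_id, lesion_id, day) at row(s): ",
         paste(dup, collapse = ", "))
  if (length(visit_days) < 1L || visit_days[1L] != 0L ||
      (length(visit_days) > 1L && any(diff(visit_days) <= 0L)))
    stop("visit_days must be strictly increasing and start at 0")
  off <- which(!(m$day %in% visit_days))
  if (length(off))
    stop("measurement day not in visit schedule at row(s): ",
         paste(off, collapse = ", "))

  m <- m[order(m$patient_id, m$lesion_id, m$day), , drop = FALSE]
  rownames(m) <- NULL
  structure(list(measurements = m, visit_days = visit_days,
                 arm_label = as.character(arm_label)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("lesion_cohort%s: %d patients, %d lesions, %d measurements\n",
              if (nzchar(x$arm_label)) paste0(" [", x$arm_label, "]") else "",
              length(unique(m$patient_id)),
              nrow(unique(m[c("patient_id", "lesion_id")])), nrow(m)))
  cat("  visit days:", paste(x$visit_days, collapse = ", "), "\n")
  invisible(x)
}

#' Read a lesion cohort from CSV
#'
#' Expects a long-format table; non-canonical column names are handled via
#' `schema`, a named character vector mapping canonical names to the file's
#' names (e.g. `c(patient_id = "USUBJID", diameter_mm = "LDIAM")`).
#'
#' @param path CSV file path.
#' @param schema Named character vector; names are canonical column names,
#'   values the file's. Unmapped canonical names are looked up verbatim.
#' @param visit_days,arm_label Passed to [lesion_cohort()].
#' @return A `lesion_cohort`.
#' @export
read_cohort <- function(path, schema = character(), visit_days = NULL,
                        arm_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  canon <- c("patient_id", "lesion_id", "day", "diameter_mm")
  cols <- stats::setNames(canon, canon)
  cols[names(schema)] <- schema
  absent <- cols[!(cols %in% names(raw))]
  if (length(absent))
    stop("schema error: column(s) not found in file: ",
         paste(sprintf("%s (for %s)", absent, names(absent)), collapse = ", "))
  m <- stats::setNames(raw[, unname(cols), drop = FALSE], names(cols))
  lesion_cohort(m, visit_days = visit_days, arm_label = arm_label)
}

#' Write a lesion cohort to CSV
#'
#' Writes the canonical long format (`patient_id, lesion_id, day,
#' diameter_mm`); [read_cohort()] on the result reproduces the dataset
#' field-for-field (given the same `visit_days`).
#'
#' @param cohort A `lesion_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  utils::write.csv(cohort$measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

recist_category <- function(sld, baseline_sld, all_zero,
                            pr_threshold = -30, pd_threshold = 20) {
  pct <- if (baseline_sld > 0) 100 * (sld - baseline_sld) / baseline_sld else NA_real_
  if (all_zero) "CR"
  else if (!is.na(pct) && pct <= pr_threshold) "PR"
  else if (!is.na(pct) && pct >= pd_threshold) "PD"
  else "SD"
}

#' Per-patient RECIST-style summary at one visit
#'
#' For every patient measured at `day`, computes the sum of longest
#' diameters (SLD), the percent change from the day-0 SLD, and the response
#' category: CR when every target-lesion diameter is 0, PR when the change
#' is <= `pr_threshold` (%), PD when >= `pd_threshold` (%), SD otherwise.
#' The default thresholds are the RECIST 1.1 target-lesion values (-30, +20);
#' change is referenced to baseline, which at the first on-treatment visit
#' coincides with the nadir.
#'
#' @param cohort A `lesion_cohort`.
#' @param day A scheduled visit day present in `cohort$visit_days`.
#' @param pr_threshold,pd_threshold Percent-change cut-offs.
#' @return data.frame with columns `patient_id`, `day`, `sld_mm`,
#'   `pct_change_from_baseline`, `recist_category`.
#' @export
summarize_visit <- function(cohort, day, pr_threshold = -30,
                            pd_threshold = 20) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  if (!(day %in% cohort$visit_days))
    stop("day ", day, " is not a scheduled visit day")
  m <- cohort$measurements
  at <- m[m$day == day, , drop = FALSE]
  base <- m[m$day == 0L, , drop = FALSE]
  pats <- unique(at$patient_id)
  no_base <- setdiff(pats, unique(base$patient_id))
  if (length(no_base))
    stop("patient(s) missing baseline (day 0) measurements: ",
         paste(no_base, collapse = ", "))
  out <- do.call(rbind, lapply(pats, function(p) {
    di <- at$diameter_mm[at$patient_id == p]
    sld <- sum(di)
    bsl <- sum(base$diameter_mm[base$patient_id == p])
    pct <- if (bsl > 0) 100 * (sld - bsl) / bsl else NA_real_
    data.frame(patient_id = p, day = as.integer(day), sld_mm = sld,
               pct_change_from_baseline = pct,
               recist_category = recist_category(sld, bsl, all(di == 0),
                                                 pr_threshold, pd_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Objective response rate, percent
#'
#' ORR = 100 x (#CR + #PR) / #patients, reported to the nearest integer
#' percent (half-up), the display convention of trial summary tables.
#'
#' @param summaries data.frame from [summarize_visit()] (uses its
#'   `recist_category` column).
#' @return Integer percent.
#' @seealso [orr_from_counts()] for printed-count inputs.
#' @export
orr_percent <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("empty summary collection: ORR undefined")
  orr_from_counts(sum(summaries$recist_category %in% c("CR", "PR")),
                  nrow(summaries))
}

#' ORR percent from responder counts
#'
#' @param n_responders Number of CR + PR patients.
#' @param n_patients Total patients (> 0).
#' @return Nearest-integer percent (half-up).
#' @export
orr_from_counts <- function(n_responders, n_patients) {
  stopifnot(n_patients > 0, n_responders >= 0, n_responders <= n_patients)
  floor(100 * n_responders / n_patients + 0.5)
}

#' Keep patients who respond or stabilise at their first on-treatment visit
#'
#' The modelling cohort is restricted to patients whose first on-treatment
#' assessment is SD, PR or CR — the analysis targets response followed by
#' resistant re-growth, so primary-progression patients are excluded. Each
#' patient is classified at the smallest day > 0 at which they have any
#' measurement; patients with no on-treatment measurement are dropped.
#' Idempotent: re-applying the filter changes nothing.
#'
#' @param cohort A `lesion_cohort`.
#' @param pr_threshold,pd_threshold Percent-change cut-offs, as in
#'   [summarize_visit()].
#' @return A `lesion_cohort` containing all measurements of retained
#'   patients (possibly empty).
#' @export
filter_responders <- function(cohort, pr_threshold = -30, pd_threshold = 20) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  m <- cohort$measurements
  keep <- vapply(unique(m$patient_id), function(p) {
    dp <- m[m$patient_id == p, , drop = FALSE]
    on_tx <- sort(unique(dp$day[dp$day > 0L]))
    if (!length(on_tx)) return(FALSE)
    first <- on_tx[1L]
    di <- dp$diameter_mm[dp$day == first]
    bsl <- sum(dp$diameter_mm[dp$day == 0L])
    cat_first <- recist_category(sum(di), bsl, all(di == 0),
                                 pr_threshold, pd_threshold)
    cat_first %in% c("CR", "PR", "SD")
  }, logical(1L))
  kept <- m[m$patient_id %in% unique(m$patient_id)[keep], , drop = FALSE]
  lesion_cohort(kept, visit_days = cohort$visit_days,
                arm_label = cohort$arm_label)
}
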