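#' Specify the mixed-effects structure of the piecewise lesion model
#'
#' Two hierarchies are supported. `lesion_only` treats every lesion as an
#' independent unit (no patient information). `patient_lesion` nests lesions
#' within patients and adds patient-level random deviations for the decay
#' and re-growth slopes on top of the lesion-level ones. The baseline
#' diameter enters as `exp(lbsl_pop + b)` with `b` a lesion-level normal
#' deviate (a log-normal baseline, guaranteeing positivity); slopes are
#' normal; all random effects are mutually independent (diagonal
#' covariance), and a single residual SD is shared across all observations.
#' The switch point `sp` is one fixed value for the whole dataset — letting
#' it vary by lesion is not identifiable on sparse imaging schedules — and
#' is chosen externally over midpoint candidates (see [select_sp()]).
#'
#' @param hierarchy `"patient_lesion"` or `"lesion_only"`.
#' @param sp Switch point in days (> 0), fixed for the fit.
#' @param re_lesion Lesion-level random-effect terms, subset of
#'   `c("bsl", "decay", "regrowth")`. Dropping `"bsl"` (all lesions share
#'   one baseline) is permitted only for linearised checks and warns.
#' @param re_patient Patient-level terms, subset of `c("decay", "regrowth")`;
#'   ignored (forced empty) under `lesion_only`.
#' @return Object of class `lesion_model_spec`.
#' @export
#' @examples
#' lesion_model_spec("patient_lesion", sp = 63)
lesion_model_spec <- function(hierarchy = c("patient_lesion", "lesion_only"),
                              sp,
                              re_lesion = c("bsl", "decay", "regrowth"),
                              re_patient = NULL) {
  hierarchy <- match.arg(hierarchy)
  stopifnot(is.numeric(sp), length(sp) == 1L, sp > 0)
  re_lesion <- match.arg(re_lesion, c("bsl", "decay", "regrowth"),
                         several.ok = TRUE)
  if (is.null(re_patient))
    re_patient <- if (hierarchy == "patient_lesion") c("decay", "regrowth")
                  else character()
  if (length(re_patient))
    re_patient <- match.arg(re_patient, c("decay", "regrowth"),
                            several.ok = TRUE)
  if (hierarchy == "lesion_only" && length(re_patient)) {
    re_patient <- character()
  }
  if (!("bsl" %in% re_lesion))
    warning("no lesion-level baseline random effect: all lesions share one ",
            "baseline; intended for linearised cross-checks only")
  structure(list(hierarchy = hierarchy, sp = sp,
                 re_lesion = re_lesion, re_patient = re_patient),
            class = "lesion_model_spec")
}

#' @export
print.lesion_model_spec <- function(x, ...) {
  cat(sprintf("lesion_model_spec: hierarchy %s, switch day %g\n",
              x$hierarchy, x$sp))
  cat("  lesion-level RE:", paste(x$re_lesion, collapse = ", "), "\n")
  if (length(x$re_patient))
    cat("  patient-level RE:", paste(x$re_patient, collapse = ", "), "\n")
  invisible(x)
}

# Names of the free parameters of a spec, in canonical order.
theta_names <- function(spec) {
  nm <- c("lbsl_pop", "decay_pop", "regrowth_pop")
  if ("bsl" %in% spec$re_lesion) nm <- c(nm, "log_sd_bsl")
  if ("decay" %in% spec$re_patient) nm <- c(nm, "log_sd_decay_patient")
  if ("regrowth" %in% spec$re_patient) nm <- c(nm, "log_sd_regrowth_patient")
  if ("decay" %in% spec$re_lesion) nm <- c(nm, "log_sd_decay_lesion")
  if ("regrowth" %in% spec$re_lesion) nm <- c(nm, "log_sd_regrowth_lesion")
  c(nm, "log_sd_resid")
}

# Map a named theta vector to the SD scale used by the likelihood kernels.
theta_to_sds <- function(theta, spec) {
  gv <- function(nm) if (nm %in% names(theta)) exp(unname(theta[nm])) else 0
  list(beta0 = unname(theta["lbsl_pop"]),
       d_pop = unname(theta["decay_pop"]),
       g_pop = unname(theta["regrowth_pop"]),
       sd_b = gv("log_sd_bsl"),
       sd_pd = gv("log_sd_decay_patient"),
       sd_pg = gv("log_sd_regrowth_patient"),
       sd_ld = gv("log_sd_decay_lesion"),
       sd_lg = gv("log_sd_regrowth_lesion"),
       sd_e = exp(unname(theta["log_sd_resid"])))
}

check_theta <- function(theta, spec) {
  nm <- theta_names(spec)
  if (!all(nm %in% names(theta)))
    stop("theta lacks parameter(s): ",
         paste(setdiff(nm, names(theta)), collapse = ", "))
  if (any(!is.finite(theta[nm])))
    stop("theta contains non-finite values (SDs are log-parameterised ",
         "and must be finite)")
  theta[nm]
}

# Group a cohort's measurements into contiguous unit/lesion blocks and the
# piecewise basis at the spec's switch point. Units are patients under
# patient_lesion, single lesions under lesion_only.
prepare_pw_data <- function(cohort, spec) {
  stopifnot(inherits(cohort, "lesion_cohort"),
            inherits(spec, "lesion_model_spec"))
  m <- cohort$measurements
  if (nrow(m) == 0L) stop("empty dataset")
  # constructor sorts by patient, lesion, day; lesions are contiguous
  les_key <- paste(m$patient_id, m$lesion_id, sep = "\r")
  les_levels <- unique(les_key)
  les_f <- factor(les_key, levels = les_levels)
  les_n <- as.integer(table(les_f))
  lesion_ptr <- c(0L, cumsum(les_n))

  first_of_lesion <- match(les_levels, les_key)
  les_patient <- m$patient_id[first_of_lesion]
  if (spec$hierarchy == "patient_lesion") {
    unit_of_lesion <- factor(les_patient, levels = unique(les_patient))
  } else {
    unit_of_lesion <- factor(seq_along(les_levels))
  }
  unit_les_ptr <- c(0L, cumsum(as.integer(table(unit_of_lesion))))

  list(y = m$diameter_mm,
       x1 = pmin(m$day, spec$sp),
       x2 = pmax(m$day - spec$sp, 0),
       lesion_ptr = lesion_ptr,
       unit_les_ptr = unit_les_ptr,
       lesions = data.frame(patient_id = les_patient,
                            lesion_id = m$lesion_id[first_of_lesion],
                            stringsAsFactors = FALSE),
       n_obs = nrow(m),
       n_lesions = length(les_levels),
       n_units = length(levels(unit_of_lesion)),
       n_patients = length(unique(m$patient_id)))
}
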