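# Post-fit variability and diagnostic reports: CV decomposition of the
# kinetic rates, decay-vs-regrowth correlation with sign-anomaly counts,
# observed-vs-fitted concordance, and arm-level summary tables.

#' Coefficient-of-variation table of the kinetic rates
#'
#' For each slope (decay, regrowth) and each level present in the fitted
#' hierarchy, CV = SD / |population mean| — the |mean| because decay means
#' are negative; the sign travels in the `mean` column. Between-patient CV
#' uses the patient-level SD, within-patient CV the lesion-level SD. A
#' population mean of 0 leaves the CV undefined: the entry is flagged and
#' `cv` set `NA` rather than infinite.
#'
#' @param fit A converged [fit_lesion_model()] result.
#' @return data.frame `parameter`, `level` (`between_patient` /
#'   `within_patient`), `mean`, `sd`, `cv`, `flagged`.
#' @export
cv_table <- function(fit) {
  stopifnot(inherits(fit, "lesion_fit"))
  if (!fit$converged) stop("fit did not converge; CV table unavailable")
  vc <- fit$variance_components
  fe <- fit$fixed_effects
  get_sd <- function(term, level) {
    i <- vc$term == term & vc$level == level
    if (any(i)) vc$sd[i] else NA_real_
  }
  row <- function(par, level, lvl_label) {
    mu <- unname(fe[[paste0(par, "_pop")]])
    s <- get_sd(par, level)
    if (is.na(s)) return(NULL)
    flag <- mu == 0
    data.frame(parameter = par, level = lvl_label, mean = mu, sd = s,
               cv = if (flag) NA_real_ else s / abs(mu), flagged = flag,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("decay", "patient", "between_patient"),
               row("decay", "lesion", "within_patient"),
               row("regrowth", "patient", "between_patient"),
               row("regrowth", "lesion", "within_patient"))
  rownames(out) <- NULL
  out
}

#' Correlation between per-lesion decay and re-growth rates
#'
#' Regresses the per-lesion re-growth estimates on the decay estimates by
#' ordinary least squares and reports the coefficient of determination,
#' together with the fractions of sign-anomalous lesions (positive decay:
#' growing during the "shrinkage" phase; negative regrowth: still shrinking
#' after the switch). The default estimator is the empirical-Bayes table of
#' the fit; EB shrinkage can attenuate r-squared, so raw per-lesion least
#' squares (`estimator = "ols"`, lesions with enough observations only) is
#' available as an alternative.
#'
#' @param fit A converged [fit_lesion_model()] result.
#' @param cohort Required for `estimator = "ols"`: the fitted cohort.
#' @param estimator `"eb"` (default) or `"ols"`.
#' @return List of class `correlation_report`: `r_squared`, `n_lesions`,
#'   `fraction_positive_decay`, `fraction_negative_regrowth`, `estimator`,
#'   `flagged` (TRUE when a zero-variance axis leaves r-squared undefined).
#' @export
decay_regrowth_correlation <- function(fit, cohort = NULL,
                                       estimator = c("eb", "ols")) {
  stopifnot(inherits(fit, "lesion_fit"))
  estimator <- match.arg(estimator)
  if (estimator == "eb") {
    if (is.null(fit$eb_estimates)) stop("fit carries no EB estimates")
    d <- fit$eb_estimates$decay
    g <- fit$eb_estimates$regrowth
  } else {
    if (is.null(cohort)) stop("estimator = \"ols\" needs the cohort")
    pd <- prepare_pw_data(cohort, fit$spec)
    lp <- pd$lesion_ptr
    d <- g <- rep(NA_real_, pd$n_lesions)
    for (j in seq_len(pd$n_lesions)) {
      idx <- (lp[j] + 1L):lp[j + 1L]
      X <- cbind(1, pd$x1[idx], pd$x2[idx])
      if (length(idx) >= 3L && qr(X)$rank == 3L) {
        cf <- stats::lm.fit(X, pd$y[idx])$coefficients
        d[j] <- cf[2]; g[j] <- cf[3]
      }
    }
    keep <- is.finite(d) & is.finite(g)
    d <- d[keep]; g <- g[keep]
  }
  if (length(d) < 3L)
    stop("need >= 3 lesions with both slope estimates")
  flagged <- stats::sd(d) == 0 || stats::sd(g) == 0
  r2 <- if (flagged) NA_real_ else stats::cor(d, g)^2
  structure(list(r_squared = r2, n_lesions = length(d),
                 fraction_positive_decay = mean(d > 0),
                 fraction_negative_regrowth = mean(g < 0),
                 estimator = estimator, flagged = flagged),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("decay vs re-growth across %d lesions (%s estimates): r^2 = %s\n",
              x$n_lesions, x$estimator,
              if (x$flagged) "undefined (zero variance)" else
                sprintf("%.4f", x$r_squared)))
  cat(sprintf("  sign anomalies: %.1f%% positive decay, %.1f%% negative regrowth\n",
              100 * x$fraction_positive_decay,
              100 * x$fraction_negative_regrowth))
  invisible(x)
}

#' Observed-versus-fitted diagnostic table
#'
#' Pairs every observed diameter with the fitted value from the lesion's
#' empirical-Bayes parameters (the structural piecewise prediction at the
#' EB baseline and slopes) and reports concordance about the line of unity:
#' R-squared computed as `1 - SS(obs - fit) / SS(obs - mean(obs))`, and the
#' mean absolute error.
#'
#' @param cohort The fitted [lesion_cohort()].
#' @param fit The [fit_lesion_model()] result for that cohort.
#' @return List of class `observed_vs_fitted`: `pairs` data.frame
#'   (`patient_id`, `lesion_id`, `day`, `observed`, `fitted`), `r_squared`,
#'   `mae`, `n_obs`.
#' @export
observed_vs_fitted <- function(cohort, fit) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(fit, "lesion_fit"))
  if (is.null(fit$eb_estimates)) stop("fit carries no EB estimates")
  m <- cohort$measurements
  if (nrow(m) != fit$n_obs)
    stop("dataset does not match the fit (observation count differs)")
  eb <- fit$eb_estimates
  key <- paste(m$patient_id, m$lesion_id, sep = "\r")
  ek <- paste(eb$patient_id, eb$lesion_id, sep = "\r")
  idx <- match(key, ek)
  if (anyNA(idx))
    stop("dataset does not match the fit (unknown lesion present)")
  x1 <- pmin(m$day, fit$sp_used)
  x2 <- pmax(m$day - fit$sp_used, 0)
  fitted <- eb$bsl[idx] + eb$decay[idx] * x1 + eb$regrowth[idx] * x2
  obs <- m$diameter_mm
  pairs <- data.frame(patient_id = m$patient_id, lesion_id = m$lesion_id,
                      day = m$day, observed = obs, fitted = fitted,
                      stringsAsFactors = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  structure(list(pairs = pairs,
                 r_squared = 1 - sum((obs - fitted)^2) / ss_tot,
                 mae = mean(abs(obs - fitted)),
                 n_obs = nrow(m)),
            class = "observed_vs_fitted")
}

#' @export
print.observed_vs_fitted <- function(x, ...) {
  cat(sprintf("observed vs fitted over %d measurements: unity-line R^2 = %.4f, MAE = %.3f mm\n",
              x$n_obs, x$r_squared, x$mae))
  invisible(x)
}

#' Arm-level imaging summary
#'
#' The standard trial-report table for one arm: patient count, median and
#' quartiles of the baseline sum of longest diameters (SLD) and of the
#' individual lesion diameters (ILD), and — at the first on-treatment visit
#' ("week 6" on the default schedule) — the objective response rate and the
#' median and quartiles of the percent SLD change. Quantiles use linear
#' interpolation between order statistics (R's default type 7); this
#' convention is pinned because published-table comparisons depend on it.
#' With no on-treatment visit the response fields are `NA` and `partial`
#' is TRUE.
#'
#' @param cohort A [lesion_cohort()].
#' @param pr_threshold,pd_threshold Percent-change cut-offs, as in
#'   [summarize_visit()].
#' @return List of class `arm_summary` with fields `arm_label`,
#'   `n_patients`, `sld_baseline` and `ild_baseline` (named `median`/`q25`/
#'   `q75` vectors), `first_on_treatment_day`, `orr_n`, `orr_percent`,
#'   `pct_change_sld` (median/q25/q75), `partial`.
#' @export
arm_summary <- function(cohort, pr_threshold = -30, pd_threshold = 20) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  m <- cohort$measurements
  base <- m[m$day == 0L, , drop = FALSE]
  if (nrow(base) == 0L) stop("no baseline (day 0) measurements")
  q3 <- function(x) setNames(quantile(x, c(0.5, 0.25, 0.75), type = 7),
                             c("median", "q25", "q75"))
  sld0 <- tapply(base$diameter_mm, base$patient_id, sum)
  on_days <- sort(unique(m$day[m$day > 0L]))
  out <- list(arm_label = cohort$arm_label,
              n_patients = length(unique(m$patient_id)),
              sld_baseline = q3(sld0),
              ild_baseline = q3(base$diameter_mm),
              first_on_treatment_day = if (length(on_days)) on_days[1L] else NA,
              orr_n = NA_integer_, orr_percent = NA_real_,
              pct_change_sld = setNames(rep(NA_real_, 3),
                                        c("median", "q25", "q75")),
              partial = !length(on_days))
  if (length(on_days)) {
    sv <- summarize_visit(cohort, on_days[1L], pr_threshold, pd_threshold)
    out$orr_n <- sum(sv$recist_category %in% c("CR", "PR"))
    out$orr_percent <- orr_percent(sv)
    out$pct_change_sld <- q3(sv$pct_change_from_baseline)
  }
  structure(out, class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("arm summary%s: N = %d patients\n",
              if (nzchar(x$arm_label)) paste0(" [", x$arm_label, "]") else "",
              x$n_patients))
  cat(sprintf("  baseline SLD mm: %.0f (%.0f, %.0f);  ILD mm: %.0f (%.0f, %.0f)\n",
              x$sld_baseline["median"], x$sld_baseline["q25"],
              x$sld_baseline["q75"], x$ild_baseline["median"],
              x$ild_baseline["q25"], x$ild_baseline["q75"]))
  if (x$partial) {
    cat("  no on-treatment visit: response summaries unavailable\n")
  } else {
    cat(sprintf("  first on-treatment visit day %d: ORR %d (%d%%); %%SLD change %.0f (%.0f, %.0f)\n",
                x$first_on_treatment_day, x$orr_n, x$orr_percent,
                x$pct_change_sld["median"], x$pct_change_sld["q25"],
                x$pct_change_sld["q75"]))
  }
  invisible(x)
}
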