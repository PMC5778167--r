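# Post-fit variability decomposition, correlation and diagnostics.

make_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_cohort(synthetic_config(n_patients = 150, seed = 6))
      fit <- fit_lesion_model(sim$cohort,
                              lesion_model_spec("patient_lesion", sp = 63))
      cache <<- list(sim = sim, fit = fit)
    }
    cache
  }
})

test_that("CV table divides each level's SD by the absolute population mean", {
  x <- make_fit()
  cv <- cv_table(x$fit)
  expect_setequal(cv$level, c("between_patient", "within_patient"))
  vc <- x$fit$variance_components
  d_mean <- x$fit$fixed_effects[["decay_pop"]]
  expect_equal(cv$cv[cv$parameter == "decay" & cv$level == "between_patient"],
               vc$sd[vc$term == "decay" & vc$level == "patient"] / abs(d_mean))
  expect_true(all(cv$cv >= 0))
  # fitted CVs recover the generator's CVs (truth 0.294 / 0.286)
  st <- summarize_truth(x$sim$truth)
  for (i in seq_len(nrow(cv))) {
    truth_cv <- st$cv$cv[st$cv$parameter == cv$parameter[i] &
                           st$cv$level == cv$level[i]]
    expect_equal(cv$cv[i], truth_cv, tolerance = 0.30)
  }
})

test_that("decay-regrowth correlation handles exact relations, independence and anomalies", {
  x <- make_fit()
  # perfect linear relation gives r^2 = 1 (construct a doctored fit table)
  doctored <- x$fit
  doctored$eb_estimates$regrowth <- 2 * doctored$eb_estimates$decay
  expect_equal(decay_regrowth_correlation(doctored)$r_squared, 1)
  # independent generator: low r^2 at moderate n already
  cr <- decay_regrowth_correlation(x$fit)
  expect_lt(cr$r_squared, 0.2)
  expect_equal(cr$n_lesions, x$fit$n_lesions)
  # anomaly fractions equal brute-force counts over the EB table
  eb <- x$fit$eb_estimates
  expect_equal(cr$fraction_positive_decay, sum(eb$decay > 0) / nrow(eb))
  expect_equal(cr$fraction_negative_regrowth, sum(eb$regrowth < 0) / nrow(eb))
  # r^2 is invariant to affine rescaling of either axis
  sc <- x$fit
  sc$eb_estimates$decay <- 3.2 * sc$eb_estimates$decay - 1
  expect_equal(decay_regrowth_correlation(sc)$r_squared, cr$r_squared)
  # zero-variance axis is flagged, not crashed
  flat <- x$fit
  flat$eb_estimates$regrowth <- 0.07
  expect_true(decay_regrowth_correlation(flat)$flagged)
})

test_that("noiseless zero-variance cohorts produce anomaly-free, exact fits", {
  cfg <- synthetic_config(n_patients = 10, seed = 3, bsl_log_sd = 0,
                          decay_sd_between = 0, decay_sd_within = 0,
                          regrowth_sd_between = 0, regrowth_sd_within = 0,
                          residual_sd = 0)
  sim <- simulate_cohort(cfg)
  fit <- fit_lesion_model(sim$cohort, lesion_model_spec("patient_lesion", sp = 63))
  cr <- decay_regrowth_correlation(fit)
  expect_equal(cr$fraction_positive_decay, 0)
  expect_equal(cr$fraction_negative_regrowth, 0)
  ovf <- observed_vs_fitted(sim$cohort, fit)
  expect_lt(ovf$mae, 1e-6)
})

test_that("fitted values equal the piecewise prediction at the EB parameters", {
  x <- make_fit()
  ovf <- observed_vs_fitted(x$sim$cohort, x$fit)
  eb <- x$fit$eb_estimates
  # recompute independently through the structural model
  idx <- sample(nrow(ovf$pairs), 40)
  for (i in idx) {
    row <- ovf$pairs[i, ]
    e <- eb[eb$patient_id == row$patient_id & eb$lesion_id == row$lesion_id, ]
    p <- piecewise_params(e$bsl, e$decay, e$regrowth, e$sp)
    expect_equal(row$fitted, predict_diameter(p, row$day), tolerance = 1e-10)
  }
  expect_gt(ovf$r_squared, 0.9)
  # mismatched dataset is refused
  other <- simulate_cohort(synthetic_config(n_patients = 3, seed = 99))$cohort
  expect_error(observed_vs_fitted(other, x$fit), "does not match")
})

test_that("unity-line concordance degrades monotonically with residual noise", {
  r2 <- vapply(c(0.5, 3, 8), function(s) {
    sim <- simulate_cohort(synthetic_config(n_patients = 60, seed = 4,
                                            residual_sd = s))
    fit <- fit_lesion_model(sim$cohort,
                            lesion_model_spec("patient_lesion", sp = 63),
                            control = quick_control)
    observed_vs_fitted(sim$cohort, fit)$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
})

test_that("arm summaries use type-7 quantiles and report response at the first visit", {
  m <- data.frame(patient_id = "p1", lesion_id = c("l1", "l2"),
                  day = 0L, diameter_mm = c(30, 40))
  s <- arm_summary(lesion_cohort(m, visit_days = 0L))
  expect_equal(unname(s$sld_baseline["median"]), 70)
  expect_equal(unname(s$ild_baseline["median"]), 35)
  expect_true(s$partial)
  # pinned percentile convention: type-7 linear interpolation
  expect_equal(unname(quantile(c(10, 20, 30, 40), 0.25, type = 7)), 17.5)
  m4 <- data.frame(patient_id = rep(c("a", "b", "c", "d"), each = 1),
                   lesion_id = "l1", day = 0L,
                   diameter_mm = c(10, 20, 30, 40))
  s4 <- arm_summary(lesion_cohort(m4, visit_days = 0L))
  expect_equal(unname(s4$ild_baseline["q25"]), 17.5)

  sim <- simulate_cohort(synthetic_config(n_patients = 300, seed = 10))
  sa <- arm_summary(sim$cohort)
  expect_equal(sa$first_on_treatment_day, 42L)
  expect_equal(sa$orr_percent,
               orr_percent(summarize_visit(sim$cohort, 42L)))
  expect_false(sa$partial)
})
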