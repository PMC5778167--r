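# The marginal likelihood: backend agreement, closed-form limits,
# factorisation, and an external mixed-model cross-check.

test_that("with all random-effect SDs at zero the marginal equals the OLS Gaussian log-likelihood", {
  sim <- simulate_cohort(synthetic_config(n_patients = 6, seed = 11))
  spec <- lesion_model_spec("lesion_only", sp = 63)
  th <- c(lbsl_pop = log(20), decay_pop = -0.17, regrowth_pop = 0.07,
          log_sd_bsl = -40, log_sd_decay_lesion = -40,
          log_sd_regrowth_lesion = -40, log_sd_resid = log(1.5))
  m <- sim$cohort$measurements
  mu <- 20 - 0.17 * pmin(m$day, 63) + 0.07 * pmax(m$day - 63, 0)
  closed <- sum(dnorm(m$diameter_mm, mu, 1.5, log = TRUE))
  for (method in c("agq", "laplace"))
    expect_equal(as.numeric(marginal_loglik(sim$cohort, spec, th, method)),
                 closed, tolerance = 1e-10)
})

test_that("single lesion with random baseline: quadrature matches brute-force integration", {
  coh <- lesion_cohort(data.frame(patient_id = "p1", lesion_id = "l1",
                                  day = c(0L, 42L), diameter_mm = c(22, 14)),
                       visit_days = c(0L, 42L))
  spec <- lesion_model_spec("lesion_only", sp = 63, re_lesion = "bsl")
  th <- c(lbsl_pop = log(20), decay_pop = -0.17, regrowth_pop = 0.07,
          log_sd_bsl = log(0.4), log_sd_resid = log(1.5))
  f <- function(b) vapply(b, function(bb) {
    mu <- exp(log(20) + bb) - 0.17 * c(0, 42)
    exp(sum(dnorm(c(22, 14), mu, 1.5, log = TRUE)) +
          dnorm(bb, 0, 0.4, log = TRUE))
  }, numeric(1))
  brute <- log(integrate(f, -8, 8, rel.tol = 1e-12)$value)
  expect_equal(as.numeric(marginal_loglik(coh, spec, th, "ghq",
                                          ghq_points = 61)),
               brute, tolerance = 1e-9)
  expect_equal(as.numeric(marginal_loglik(coh, spec, th, "agq")),
               brute, tolerance = 1e-7)
  # the single-node mode-centred (Laplace-type) value sits within 1e-2
  expect_equal(as.numeric(marginal_loglik(coh, spec, th, "laplace")),
               brute, tolerance = 1e-2)
})

test_that("duplicating a patient adds exactly that patient's own contribution", {
  sim <- simulate_cohort(synthetic_config(n_patients = 3, seed = 4))
  spec <- lesion_model_spec("patient_lesion", sp = 63)
  th <- truth_theta()
  ll1 <- marginal_loglik(sim$cohort, spec, th)
  m <- sim$cohort$measurements
  extra <- m[m$patient_id == "P0002", ]
  extra$patient_id <- "P9999"
  coh2 <- lesion_cohort(rbind(m, extra), visit_days = sim$cohort$visit_days)
  ll2 <- marginal_loglik(coh2, spec, th)
  per_unit <- attr(ll1, "unit_loglik")
  expect_equal(as.numeric(ll2), as.numeric(ll1) + per_unit[2],
               tolerance = 1e-8)
})

test_that("compiled backend agrees with the pure-R dense quadrature oracle", {
  # several random instances; units capped at 3 lesions for the dense rule
  for (seed in 1:4) {
    cfg <- synthetic_config(n_patients = 3, seed = seed,
                            lesion_count_pmf = c(0.4, 0.3, 0.3, 0, 0, 0, 0))
    sim <- simulate_cohort(cfg)
    spec <- lesion_model_spec("patient_lesion", sp = 63)
    set.seed(seed)
    th <- truth_theta() + rnorm(9, 0, 0.05)
    agq <- marginal_loglik(sim$cohort, spec, th, "agq")
    ghq <- marginal_loglik(sim$cohort, spec, th, "ghq", ghq_points = 21)
    expect_equal(as.numeric(agq), as.numeric(ghq), tolerance = 1e-5)
  }
})

test_that("the linearised model reproduces lme4's maximised Gaussian marginal", {
  skip_if_not_installed("lme4")
  # all lesions share one baseline (no baseline random effect): the model
  # is an ordinary linear mixed model; evaluate our marginal at lme4's ML
  # estimates and compare with lme4's own log-likelihood
  cfg <- synthetic_config(n_patients = 40, seed = 9, bsl_log_sd = 0)
  sim <- simulate_cohort(cfg)
  m <- sim$cohort$measurements
  d <- data.frame(y = m$diameter_mm,
                  x1 = pmin(m$day, 63), x2 = pmax(m$day - 63, 0),
                  patient = m$patient_id,
                  lesion = paste(m$patient_id, m$lesion_id))
  lf <- lme4::lmer(y ~ x1 + x2 + (0 + x1 + x2 || patient) +
                     (0 + x1 + x2 || lesion),
                   data = d, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nRE = "ignore", calc.derivs = FALSE))
  vc <- as.data.frame(lme4::VarCorr(lf))
  getsd <- function(grp, var) {
    # the double-bar expansion names groups "lesion", "lesion.1", ...
    s <- vc$sdcor[startsWith(vc$grp, grp) & !is.na(vc$var1) & vc$var1 == var]
    max(c(s, 1e-300))
  }
  suppressWarnings(spec <- lesion_model_spec("patient_lesion", sp = 63,
                                             re_lesion = c("decay", "regrowth")))
  th <- c(lbsl_pop = log(unname(lme4::fixef(lf)[1])),
          decay_pop = unname(lme4::fixef(lf)["x1"]),
          regrowth_pop = unname(lme4::fixef(lf)["x2"]),
          log_sd_decay_patient = log(getsd("patient", "x1")),
          log_sd_regrowth_patient = log(getsd("patient", "x2")),
          log_sd_decay_lesion = log(getsd("lesion", "x1")),
          log_sd_regrowth_lesion = log(getsd("lesion", "x2")),
          log_sd_resid = log(stats::sigma(lf)))
  expect_equal(as.numeric(marginal_loglik(sim$cohort, spec, th, "agq")),
               as.numeric(stats::logLik(lf)), tolerance = 1e-6)
})

test_that("theta validation catches missing names and non-finite entries", {
  sim <- simulate_cohort(synthetic_config(n_patients = 2, seed = 1))
  spec <- lesion_model_spec("patient_lesion", sp = 63)
  expect_error(marginal_loglik(sim$cohort, spec, c(lbsl_pop = 3)),
               "lacks parameter")
  th <- truth_theta(); th["log_sd_resid"] <- Inf
  expect_error(marginal_loglik(sim$cohort, spec, th), "non-finite")
})
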