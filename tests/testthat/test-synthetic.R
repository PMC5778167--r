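# The seeded cohort generator: the stated statistical world downstream
# stages are validated against.

test_that("noiseless zero-variance cohorts sit exactly on the population line", {
  cfg <- synthetic_config(n_patients = 6, seed = 2, bsl_log_sd = 0,
                          decay_sd_between = 0, decay_sd_within = 0,
                          regrowth_sd_between = 0, regrowth_sd_within = 0,
                          residual_sd = 0)
  sim <- simulate_cohort(cfg)
  m <- sim$cohort$measurements
  p <- piecewise_params(exp(cfg$bsl_log_mean), cfg$decay_mean,
                        cfg$regrowth_mean, cfg$sp_true)
  expect_equal(m$diameter_mm, pmax(predict_diameter(p, m$day), 0))
})

test_that("generation is deterministic in the seed", {
  a <- simulate_cohort(synthetic_config(n_patients = 25, seed = 123))
  b <- simulate_cohort(synthetic_config(n_patients = 25, seed = 123))
  expect_identical(a$cohort$measurements, b$cohort$measurements)
  expect_identical(a$truth$lesions, b$truth$lesions)
  c2 <- simulate_cohort(synthetic_config(n_patients = 25, seed = 124))
  expect_false(identical(a$cohort$measurements, c2$cohort$measurements))
})

test_that("realised slope dispersion follows the law of total variance", {
  cfg <- synthetic_config(n_patients = 500, seed = 31)
  sim <- simulate_cohort(cfg)
  les <- sim$truth$lesions
  expect_equal(sd(les$decay),
               sqrt(cfg$decay_sd_between^2 + cfg$decay_sd_within^2),
               tolerance = 0.10)
  expect_equal(sd(les$regrowth),
               sqrt(cfg$regrowth_sd_between^2 + cfg$regrowth_sd_within^2),
               tolerance = 0.10)
  # additivity: lesion slope = population + patient deviation + lesion deviation
  pat <- sim$truth$patients
  pd <- pat$patient_dev_decay[match(les$patient_id, pat$patient_id)]
  expect_equal(les$decay, cfg$decay_mean + pd + les$lesion_dev_decay)
})

test_that("lesion counts follow the configured distribution with 80% multi-lesion", {
  cfg <- synthetic_config(n_patients = 5000, seed = 11)
  sim <- simulate_cohort(cfg)
  n_les <- sim$truth$patients$n_lesions
  expect_equal(mean(n_les > 1), 0.80, tolerance = 0.03)
  obs <- tabulate(n_les, nbins = 7)
  pmf <- cfg$lesion_count_pmf
  gof <- suppressWarnings(chisq.test(obs[pmf > 0], p = pmf[pmf > 0]))
  expect_gt(gof$p.value, 0.01)
  expect_equal(obs[6], 0L)  # six-lesion patients never occur by default
})

test_that("marginal visit means match the population prediction at scale", {
  cfg <- synthetic_config(n_patients = 3000, seed = 5)
  sim <- simulate_cohort(cfg)
  m <- sim$cohort$measurements
  bsl_mean <- exp(cfg$bsl_log_mean + cfg$bsl_log_sd^2 / 2)
  pop <- piecewise_params(bsl_mean, cfg$decay_mean, cfg$regrowth_mean,
                         cfg$sp_true)
  for (day in c(0L, 42L, 210L)) {
    obs <- m$diameter_mm[m$day == day]
    mc_se <- sd(obs) / sqrt(length(obs))
    # clipping at 0 shifts the day-42 mean up slightly; allow for it
    expect_equal(mean(obs), predict_diameter(pop, day),
                 tolerance = (4 * mc_se + 0.1) / predict_diameter(pop, day))
  }
})

test_that("ground-truth summary reports CVs, independence and anomalies", {
  cfg <- synthetic_config(n_patients = 2000, seed = 13)
  sim <- simulate_cohort(cfg)
  st <- summarize_truth(sim$truth)
  cv <- st$cv
  expect_equal(cv$cv[cv$parameter == "decay" & cv$level == "between_patient"],
               cfg$decay_sd_between / abs(cfg$decay_mean))
  # independent draws: realised correlation shrinks with n
  expect_lt(abs(st$decay_regrowth_cor), 0.05)
  expect_lt(st$decay_regrowth_r2, 0.01)
  # zero between-patient SD gives CV exactly 0
  cfg0 <- synthetic_config(n_patients = 5, seed = 1, decay_sd_between = 0)
  st0 <- summarize_truth(simulate_cohort(cfg0)$truth)
  expect_equal(st0$cv$cv[st0$cv$parameter == "decay" &
                           st0$cv$level == "between_patient"], 0)
  # zero mean flags the CV rather than returning infinity
  cfgz <- synthetic_config(n_patients = 5, seed = 1, regrowth_mean = 0)
  stz <- summarize_truth(simulate_cohort(cfgz)$truth)
  expect_true(all(stz$cv$flagged[stz$cv$parameter == "regrowth"]))
  expect_true(all(is.na(stz$cv$cv[stz$cv$parameter == "regrowth"])))
})

test_that("dropout at progression truncates series after the first PD visit", {
  cfg <- synthetic_config(n_patients = 150, seed = 21, decay_mean = 0.05,
                          dropout_at_pd = TRUE)
  sim <- simulate_cohort(cfg)
  m <- sim$cohort$measurements
  # growing cohort: many patients progress; nobody has data after their
  # first PD classification
  for (p in unique(m$patient_id)) {
    dp <- m[m$patient_id == p, ]
    bsl <- sum(dp$diameter_mm[dp$day == 0])
    days <- sort(unique(dp$day[dp$day > 0]))
    pd_seen <- FALSE
    for (d in days) {
      expect_false(pd_seen)  # no data after a PD visit
      sld <- sum(dp$diameter_mm[dp$day == d])
      if (bsl > 0 && 100 * (sld - bsl) / bsl >= 20) pd_seen <- TRUE
    }
  }
})

test_that("invalid configurations fail before any sampling", {
  expect_error(synthetic_config(n_patients = 0), "n_patients")
  expect_error(synthetic_config(lesion_count_pmf = rep(1, 7)), "summing to 1")
  expect_error(synthetic_config(residual_sd = -1), "SDs")
  expect_error(synthetic_config(visit_days = c(0, 42, 42)), "strictly increasing")
  expect_error(synthetic_config(sp_true = -5), "positive")
})
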