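# Reading, writing, RECIST-style summaries and the inclusion filter.

test_that("well-formed tables round-trip through CSV field-for-field", {
  m <- data.frame(patient_id = "p1", lesion_id = c("l1", "l2", "l1"),
                  day = c(0L, 0L, 42L), diameter_mm = c(20, 30, 10))
  coh <- lesion_cohort(m, visit_days = c(0L, 42L))
  expect_equal(nrow(coh$measurements), 3L)

  sim <- simulate_cohort(synthetic_config(n_patients = 15, seed = 77))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path, visit_days = sim$cohort$visit_days,
                      arm_label = sim$cohort$arm_label)
  expect_equal(back$measurements, sim$cohort$measurements)
  expect_equal(back$visit_days, sim$cohort$visit_days)
})

test_that("schema mapping finds renamed columns and reports missing ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(USUBJID = "p1", LESID = "l1", ADY = c(0L, 42L),
                       LDIAM = c(12, 9)), path, row.names = FALSE)
  coh <- read_cohort(path, schema = c(patient_id = "USUBJID",
                                      lesion_id = "LESID", day = "ADY",
                                      diameter_mm = "LDIAM"))
  expect_equal(coh$measurements$diameter_mm, c(12, 9))
  expect_error(read_cohort(path), "schema error.*patient_id")
})

test_that("validation rejects bad rows and names them", {
  m <- data.frame(patient_id = "p1", lesion_id = "l1",
                  day = c(0L, 42L), diameter_mm = c(20, -5))
  expect_error(lesion_cohort(m, visit_days = c(0L, 42L)), "row\\(s\\): 2")
  dup <- data.frame(patient_id = "p1", lesion_id = "l1",
                    day = c(0L, 0L), diameter_mm = c(20, 21))
  expect_error(lesion_cohort(dup, visit_days = 0L), "duplicate")
  off_schedule <- data.frame(patient_id = "p1", lesion_id = "l1",
                             day = c(0L, 40L), diameter_mm = c(20, 15))
  expect_error(lesion_cohort(off_schedule, visit_days = c(0L, 42L)),
               "not in visit schedule")
  expect_error(lesion_cohort(m[1, ], visit_days = c(5L, 42L)),
               "start at 0")
})

test_that("visit summaries compute SLD, percent change and RECIST category", {
  m <- data.frame(patient_id = "p1", lesion_id = c("l1", "l2", "l1", "l2"),
                  day = c(0L, 0L, 42L, 42L), diameter_mm = c(20, 30, 10, 18))
  coh <- lesion_cohort(m, visit_days = c(0L, 42L))
  sv <- summarize_visit(coh, 42)
  expect_equal(sv$sld_mm, 28)
  expect_equal(sv$pct_change_from_baseline, -44, tolerance = 0.01)
  expect_equal(sv$recist_category, "PR")
  # unchanged diameters are SD; complete disappearance is CR
  m2 <- m; m2$diameter_mm <- c(20, 30, 20, 30)
  expect_equal(summarize_visit(lesion_cohort(m2, c(0L, 42L)), 42)$recist_category, "SD")
  m3 <- m; m3$diameter_mm <- c(20, 30, 0, 0)
  expect_equal(summarize_visit(lesion_cohort(m3, c(0L, 42L)), 42)$recist_category, "CR")
  # missing baseline is an error naming the patient
  m4 <- data.frame(patient_id = "p9", lesion_id = "l1", day = 42L,
                   diameter_mm = 5)
  coh4 <- lesion_cohort(rbind(m, m4), visit_days = c(0L, 42L))
  expect_error(summarize_visit(coh4, 42), "p9")
})

test_that("SLD equals the brute-force per-patient sum on a generated cohort", {
  sim <- simulate_cohort(synthetic_config(n_patients = 30, seed = 3))
  m <- sim$cohort$measurements
  for (day in c(0L, 42L, 147L)) {
    sv <- summarize_visit(sim$cohort, day)
    brute <- tapply(m$diameter_mm[m$day == day], m$patient_id[m$day == day], sum)
    expect_equal(sv$sld_mm, as.numeric(brute[sv$patient_id]))
  }
})

test_that("ORR uses nearest-integer percent and rejects empty input", {
  expect_equal(orr_from_counts(121, 203), 60)
  expect_equal(orr_from_counts(104, 165), 63)
  expect_equal(orr_from_counts(46, 157), 29)
  expect_equal(orr_from_counts(0, 50), 0)
  expect_error(orr_percent(data.frame()), "empty")
  sv <- data.frame(recist_category = c("CR", "PR", "SD", "PD"))
  expect_equal(orr_percent(sv), 50)
})

test_that("responder filter keeps SD/PR/CR at the first on-treatment visit and is idempotent", {
  # p1 progresses (+25%), p2 responds (-40%), p3 has no on-treatment data
  m <- data.frame(
    patient_id = rep(c("p1", "p2", "p3"), c(2, 2, 1)),
    lesion_id = "l1",
    day = c(0L, 42L, 0L, 42L, 0L),
    diameter_mm = c(20, 25, 20, 12, 15))
  coh <- lesion_cohort(m, visit_days = c(0L, 42L))
  kept <- filter_responders(coh)
  expect_equal(unique(kept$measurements$patient_id), "p2")
  expect_equal(filter_responders(kept)$measurements, kept$measurements)

  # planted progressors in a synthetic cohort are exactly the ones removed
  cfg <- synthetic_config(n_patients = 120, seed = 8, decay_mean = 0.02,
                          decay_sd_between = 0.08, decay_sd_within = 0.08)
  sim <- simulate_cohort(cfg)
  kept <- filter_responders(sim$cohort)
  truth_pd <- sim$truth$patients$patient_id[
    sim$truth$patients$first_visit_category == "PD"]
  expect_gt(length(truth_pd), 0)  # the shifted config does plant progressors
  removed <- setdiff(unique(sim$cohort$measurements$patient_id),
                     unique(kept$measurements$patient_id))
  expect_setequal(removed, truth_pd)
  # and the filter output is a subset of the input patients
  expect_true(all(unique(kept$measurements$patient_id) %in%
                    unique(sim$cohort$measurements$patient_id)))
})
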