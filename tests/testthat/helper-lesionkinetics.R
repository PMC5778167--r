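# Shared fixtures, built in code.

# a tiny hand-written two-patient cohort on the default schedule prefix
tiny_cohort <- function() {
  m <- data.frame(
    patient_id = rep(c("p1", "p2"), c(4, 2)),
    lesion_id = c("l1", "l1", "l2", "l2", "l1", "l1"),
    day = c(0L, 42L, 0L, 42L, 0L, 42L),
    diameter_mm = c(20, 10, 30, 18, 25, 32)
  )
  lesion_cohort(m, visit_days = c(0L, 42L), arm_label = "tiny")
}

# default full theta for the patient_lesion spec at the generator's truth
truth_theta <- function(cfg = synthetic_config()) {
  c(lbsl_pop = cfg$bsl_log_mean,
    decay_pop = cfg$decay_mean,
    regrowth_pop = cfg$regrowth_mean,
    log_sd_bsl = log(max(cfg$bsl_log_sd, 1e-6)),
    log_sd_decay_patient = log(max(cfg$decay_sd_between, 1e-6)),
    log_sd_regrowth_patient = log(max(cfg$regrowth_sd_between, 1e-6)),
    log_sd_decay_lesion = log(max(cfg$decay_sd_within, 1e-6)),
    log_sd_regrowth_lesion = log(max(cfg$regrowth_sd_within, 1e-6)),
    log_sd_resid = log(max(cfg$residual_sd, 1e-6)))
}

# fast-ish fit controls for tests that only need moderate polish
quick_control <- list(refine_cycles = 3L)
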