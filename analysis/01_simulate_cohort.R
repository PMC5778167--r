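#!/usr/bin/env Rscript
# Simulate a vemurafenib-like synthetic trial arm and write it (plus its
# ground truth and a Table-1-style arm summary) under results/.
#
# The cohort generator is the package's stated statistical world: log-normal
# baseline diameters, additive patient- and lesion-level normal deviations
# on the decay and re-growth slopes, a common day-63 switch point, Gaussian
# measurement error clipped at 0 mm, imaging at days 0/42/84/147/210.

library(lesionkinetics)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(n_patients = 200, seed = seed)
print(cfg)

sim <- simulate_cohort(cfg)
message(sprintf("clipped observation fraction: %.3f", sim$truth$clipped_fraction))

# the published analyses keep only patients who are SD or better at the
# first on-treatment visit
cohort <- filter_responders(sim$cohort)
message(sprintf("responder filter: %d of %d patients retained",
                length(unique(cohort$measurements$patient_id)),
                cfg$n_patients))

write_cohort(cohort, "results/cohort.csv")
write.csv(sim$truth$lesions, "results/truth_lesions.csv", row.names = FALSE)
write.csv(sim$truth$patients, "results/truth_patients.csv", row.names = FALSE)

print(arm_summary(cohort))
sv <- summarize_visit(cohort, 42)
write.csv(sv, "results/week6_summary.csv", row.names = FALSE)
message(sprintf("week-6 ORR: %d%%; median SLD change %.1f%%",
                orr_percent(sv), median(sv$pct_change_from_baseline)))
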