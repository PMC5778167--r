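#!/usr/bin/env Rscript
# Post-fit analysis of the selected model: between-/within-patient CV
# decomposition of the kinetic rates, the decay-vs-regrowth correlation
# with sign-anomaly fractions, and observed-vs-fitted concordance. Figures
# (observed vs fitted; decay vs re-growth) go to results/ as PDFs.

library(lesionkinetics)

cohort <- read_cohort("results/cohort.csv", arm_label = "synthetic")
theta <- read.csv("results/fit_theta.csv")
sp_tab <- read.csv("results/sp_loglik_table.csv")
sel_sp <- sp_tab$sp[which.max(sp_tab$log_likelihood)]

# refit at the stored optimum (cheap: starts at the solution)
fit <- fit_lesion_model(cohort, lesion_model_spec("patient_lesion", sp = sel_sp),
                        init = setNames(theta$value, theta$parameter))

cv <- cv_table(fit)
print(cv)
write.csv(cv, "results/cv_table.csv", row.names = FALSE)

cr <- decay_regrowth_correlation(fit)
print(cr)
write.csv(data.frame(r_squared = cr$r_squared, n_lesions = cr$n_lesions,
                     fraction_positive_decay = cr$fraction_positive_decay,
                     fraction_negative_regrowth = cr$fraction_negative_regrowth),
          "results/decay_regrowth_correlation.csv", row.names = FALSE)

ovf <- observed_vs_fitted(cohort, fit)
print(ovf)
write.csv(ovf$pairs, "results/observed_vs_fitted.csv", row.names = FALSE)

pdf("results/diagnostics.pdf", width = 9, height = 4.5)
par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
lim <- range(ovf$pairs$observed, ovf$pairs$fitted)
plot(ovf$pairs$fitted, ovf$pairs$observed, pch = 16, cex = 0.4,
     col = grey(0.2, 0.35), xlim = lim, ylim = lim,
     xlab = "fitted diameter (mm)", ylab = "observed diameter (mm)",
     main = sprintf("unity-line R2 = %.3f", ovf$r_squared))
abline(0, 1, col = 2)
eb <- fit$eb_estimates
plot(eb$decay, eb$regrowth, pch = 16, cex = 0.5, col = grey(0.2, 0.5),
     xlab = "lesion decay rate (mm/day)", ylab = "lesion re-growth rate (mm/day)",
     main = sprintf("r2 = %.3f; anomalies %.1f%% / %.1f%%", cr$r_squared,
                    100 * cr$fraction_positive_decay,
                    100 * cr$fraction_negative_regrowth))
abline(h = 0, v = 0, lty = 3)
invisible(dev.off())
message("wrote results/diagnostics.pdf")
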