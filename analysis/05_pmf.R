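#!/usr/bin/env Rscript
# PMF source apportionment of the synthetic mixture: uncertainty matrix
# (EPA scheme), factor-number scan 3-6 with bootstrap mapping, final fit at
# the best factor count, and recovery of the generator's true profiles.

library(soilsrc)
samples <- read_samples("results/synthetic_samples.csv")
truth <- jsonlite::read_json("results/synthetic_truth.json",
                             simplifyVector = TRUE)
ref <- read_reference()
# simulated panel carries its own censoring MDLs
ref$mdl[names(truth$mdl)] <- pmax(unlist(truth$mdl), 1e-9)
seed <- stage_seed(20260922, "pmf")

unc <- build_uncertainty(samples, ref, scheme = "epa", error_fraction = 0.1)
cat(sprintf("uncertainty matrix: %.1f%% of cells below MDL (substituted MDL/2)\n",
            100 * mean(unc$below_mdl)))

scan <- scan_factors(unc$X, unc$U, p_range = 3:6, bootstrap_n = 20,
                     seed = seed, restarts = 5)
write.csv(scan$summary, "results/pmf_factor_scan.csv", row.names = FALSE)
print(scan$summary, digits = 4)
best_p <- scan$summary$p[which.max(scan$summary$rel_q_drop)]
cat(sprintf("largest relative Q drop at p=%d; Qrobust/Qtrue stays %.2f\n",
            best_p, max(scan$summary$ratio)))
cat("bootstrap factor mapping rates (%):\n")
print(scan$mapping)

fit <- scan$fits[[as.character(best_p)]]
write_pmf_report(fit, "results")
con <- pmf_contributions(fit)
cat("overall factor shares (%):\n")
print(round(con$overall_shares, 1))
if (best_p == nrow(truth$F)) {
  al <- align_profiles(fit$F, truth$F)
  cat(sprintf("recovered/true profile mean cosine after alignment: %.3f\n",
              al$mean_cosine))
} else {
  cat(sprintf("selected p=%d differs from the generator's %d sources\n",
              best_p, nrow(truth$F)))
}
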