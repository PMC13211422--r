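#!/usr/bin/env Rscript
# Builds the study inputs: a ground-truthed synthetic 4-source mixture with
# environmental covariates (pH planted on source 1, parent material on
# source 2), and a survey-scale table whose marginals are calibrated to the
# published Yunnan summary moments.

library(soilsrc)
dir.create("results", showWarnings = FALSE)
seed <- 20260922

mix <- generate_mixture(n = 1000, m = 8, p = 4, noise_sd = 0.05,
                        censor_rate = 0.02, seed = stage_seed(seed, "simulate"))
mix <- generate_covariates(
  mix,
  effect_map = list(pH = list(factor = 1, strength = 0.9),
                    parent_material = list(factor = 2, strength = 0.9)),
  seed = stage_seed(seed, "simulate") + 1L)
write_mixture(mix, "results")
cat(sprintf("mixture: n=%d, p=4, noise 5%%, %.1f%% cells censored, %d clipped\n",
            nrow(mix$samples), 100 * mean(mix$truth$censor_mask),
            mix$truth$n_clipped))

survey <- simulate_survey(1790, seed = stage_seed(seed, "simulate") + 2L)
write_samples(survey, "results/survey_like_samples.csv")
cat("survey-like table: n=1790, marginals calibrated to published moments\n")
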