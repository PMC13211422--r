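#!/usr/bin/env Rscript
# Descriptive statistics and the metal correlation matrix for the
# survey-like table, against the bundled Yunnan reference values.

library(soilsrc)
survey <- read_samples("results/survey_like_samples.csv")
ref <- read_reference()

summ <- summarize_metals(survey, ref)
write.csv(summ, "results/descriptive_summary.csv", row.names = FALSE)
print(summ, digits = 3)
cat(sprintf("\nhighest CV: %s (%.1f%%); metals with mean above background: %s\n",
            summ$metal[which.max(summ$cv)], max(summ$cv),
            paste(summ$metal[summ$mean > ref$background[summ$metal]],
                  collapse = ", ")))

R <- correlation_matrix(survey)
write.csv(R, "results/correlation_matrix.csv")
cat("correlation matrix written (marginals are simulated independently,\n")
cat("so off-diagonal coefficients hover near zero by construction)\n")
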