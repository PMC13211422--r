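# Shared fixtures, built in code.

# random positive sample table, lognormal marginals
random_table <- function(n, seed = 1, panel = default_panel()) {
  set.seed(seed)
  df <- as.data.frame(lapply(seq_along(panel), function(j)
    rlnorm(n, meanlog = 2 + 0.3 * j, sdlog = 0.6)))
  names(df) <- panel
  sample_table(df, panel = panel)
}

default_ref <- function() read_reference()

# moments of the published survey as named vectors
survey_vec <- function() {
  mo <- survey_moments()
  list(mean = setNames(mo$mean, mo$metal), sd = setNames(mo$sd, mo$metal),
       min = setNames(mo$min, mo$metal), max = setNames(mo$max, mo$metal))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# Planted-signal RF table: one covariate (default pH) drives the response
# through a smooth nonlinearity, the other seven are noise.
planted_rf_table <- function(n, seed, signal = "pH", noise_frac = 0.3) {
  mix <- generate_mixture(n, p = 3, noise_sd = 0.05, seed = seed)
  mix <- generate_covariates(mix, effect_map = list(), seed = seed + 1)
  df <- as.data.frame(mix$samples)
  x <- df[[signal]]
  f <- 2 * x + 0.5 * (x - mean(x))^2
  set.seed(seed + 2)
  df$Hg <- pmax(f + rnorm(n, 0, noise_frac * sd(f)), 0)
  sample_table(df)
}
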