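# soilsrc

Heavy-metal risk assessment and source apportionment for agricultural-soil
surveys, written for environmental geochemists who have a wide sample table
(one row per site, one column per metal, mg/kg) and want the standard desk
workflow end to end:

* **Pollution / risk indices** — enrichment factor
  `EF = (C_i/C_ref)/(B_i/B_ref)`, geoaccumulation index
  `Igeo = log2(C/(1.5 B))`, single-factor index `Pi = C/B`, Nemerow index
  `PN = sqrt((Pi_max² + Pi_avg²)/2)`, Hakanson risk `Ei = Ti·Pi` and
  `RI = ΣEi`, each with its published grade scale.
* **APCS-MLR** — KMO/Bartlett adequacy, varimax-rotated PCA of the
  correlation matrix, absolute principal component scores (shifted by the
  artificial zero-concentration sample), per-metal OLS
  `C_i = b0 + Σ b_k·APCS_k`, and source shares including the intercept as
  an "unknown source".
* **PMF** — from-scratch weighted non-negative factorization `X ≈ GF`
  minimizing `Q = Σ((x−GF)/u)²`, with EPA-style and piecewise measurement
  uncertainty schemes, MDL/2 substitution below the detection limit,
  `Q_true`/`Q_robust` diagnostics, a factor-number scan with bootstrap
  factor mapping, and per-metal / overall contribution shares.
* **Random-forest covariate screen** — per-metal forests over pH, N, P,
  SOC, soil type, geological time, parent material and land use, tuned by
  cross-validated R², with held-out permutation importance and the
  15 % ΔMSE flagging criterion.
* **Synthetic generator** — ground-truthed non-negative mixtures with
  multiplicative noise, MDL censoring, planted covariate effects, and a
  survey-scale simulator calibrated to published Yunnan marginal moments,
  so the whole pipeline is testable without survey data.

Bundled reference values (`inst/extdata/yunnan_reference.yml`) carry the
Yunnan Province soil backgrounds, agricultural-land screening/control
thresholds and Hakanson toxicity coefficients; swap in your own YAML for
another region.

## Worked example

Indices straight from a survey's printed summary moments and the bundled
backgrounds:

```r
library(soilsrc)
ref <- read_reference()
mo <- survey_moments()
pi_mean <- single_factor_index(setNames(mo$mean, mo$metal), ref$background[mo$metal])
pi_max  <- single_factor_index(setNames(mo$max,  mo$metal), ref$background[mo$metal])
pn <- mapply(function(mx, av) nemerow_index(pi_max = mx, pi_avg = av),
             pi_max, pi_mean)
round(rbind(pi_of_mean = pi_mean, pn = pn), 2)
#>              Hg    Cd   Pb   As   Cr    Cu   Ni   Zn
#> pi_of_mean 0.50  0.77 0.62 0.41 1.32  0.78 0.75 0.77
#> pn         3.67 11.39 2.77 2.22 4.07 24.95 4.62 7.45
```

Only Cr sits above its regional background on average (`Pi` of the mean
1.32, "mild pollution"), while the Nemerow index — which weights the worst
site — flags Cu hardest (`PN` 24.95, "severe"), driven by a 1633 mg/kg
maximum against a 46.3 mg/kg background.

PMF on a ground-truthed synthetic mixture:

```r
mix <- generate_mixture(n = 300, p = 3, noise_sd = 0.05, seed = 42)
fit <- pmf_fit(conc_matrix(mix$samples),
               pmax(0.05 * mix$truth$X_clean, 1e-9), p = 3,
               restarts = 5, seed = 1)
al <- align_profiles(fit$F, mix$truth$F)
sprintf("Q_true = %.0f, Q_robust/Q_true = %.2f, profile cosine = %.3f",
        fit$Q_true, q_values(fit)$ratio, al$mean_cosine)
#> "Q_true = 1552, Q_robust/Q_true = 1.00, profile cosine = 0.993"
```

`Q_true` lands near its degrees of freedom (300·8 − 3·308 = 1476, so
Q/dof ≈ 1.05: the uncertainties are calibrated), the robust/true ratio of
1.00 says no outlier dominates, and the recovered profiles match the
generator's truth to cosine 0.993 after optimal factor alignment.

## Analysis workflow

`analysis/01_simulate.R` … `06_rf_importance.R` are thin numbered drivers
that run the full study on generated data — simulate, descriptives,
indices, APCS-MLR, PMF scan, RF screen — printing what each stage found
and writing its tables under `results/`. `run_pipeline()` does the same in
one call with a JSON run manifest and per-stage seed fan-out.

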