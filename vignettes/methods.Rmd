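---
title: "Soil heavy-metal assessment and source apportionment: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil heavy-metal assessment and source apportionment: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilsrc)
```

This package implements the standard desk workflow for a regional
agricultural-soil heavy-metal survey: descriptive statistics and pollution /
ecological-risk indices against regional background values, receptor-model
source apportionment by APCS-MLR and by positive matrix factorization (PMF),
and a random-forest screen of environmental covariates. Because survey
matrices of this kind are rarely deposited, the package ships a
ground-truthed synthetic generator that emulates the statistical structure
every downstream stage assumes; all recovery claims in the test suite are
claims about that generator's data, a point this vignette returns to at the
end.

## Pollution and ecological-risk indices

For metal $i$ in sample $j$ with concentration $C_{ij}$ (mg/kg) and regional
background $C_{ib}$:

* **Enrichment factor** $EF = (C_{ij}/C_{ref}) / (B_i/B_{ref})$, with
  titanium as the conservative reference element. Six grades from
  "not enriched" ($EF<1$) to "very highly enriched" ($EF\ge 40$).
* **Geoaccumulation index** $I_{geo} = \log_2[C_{ij}/(1.5\,C_{ib})]$, seven
  grades from "practically unpolluted" ($I_{geo}<0$) upward; the 1.5 absorbs
  natural background fluctuation.
* **Single-factor index** $P_i = C_{ij}/C_{ib}$, five grades.
* **Nemerow index** $P_N = \sqrt{(P_{i,max}^2 + P_{i,avg}^2)/2}$ per metal
  over the region, weighting the worst site; five grades, "severe" at
  $P_N \ge 3$.
* **Ecological risk** $E_i = T_i P_i$ with Hakanson toxicity coefficients
  $T_i$ (Hg 40, Cd 30, Pb 5, As 10, Cr 2, Cu 5, Ni 5, Zn 1), and
  $RI = \sum_i E_i$ per sample, graded low ($<150$) to very high
  ($\ge 600$).

All grade intervals are left-closed/right-open exactly as conventionally
printed; `classify_index()` is the single authority for them, and a value of
exactly 0 for $I_{geo}$ falls in "unpolluted to moderately" ($0 \le I_{geo}
< 1$). Regional summaries report the *mean of per-sample index values*; by
Jensen's inequality this sits below the index of the mean concentration for
the concave $I_{geo}$, and the test suite pins that ordering down.

Conventions worth stating because the field's tables rarely do:

* standard deviations (hence CVs) use the sample $n-1$ convention —
  at survey sizes in the thousands the difference is far below reporting
  precision;
* exceedance proportions use a strict inequality ("higher than the
  background value");
* missing cells are excluded pairwise with logged counts, never imputed;
* $P_i = 0$ and $E_i = 0$ are legal (a true zero concentration), while
  $I_{geo}$ and $EF$ reject non-positive inputs, whose cells are excluded
  with a logged count;
* a sample missing any panel metal gets an `NA` RI rather than a partial
  sum, since RI is only meaningful over the full panel.

The bundled reference file carries the Yunnan Province background values,
agricultural-land screening/control thresholds and the Hakanson coefficient
list. Two entries are package conventions rather than published constants:
the titanium background (5400 mg/kg, the order of magnitude reported for
Yunnan soils — users with a regional value should replace it) and the
per-metal MDLs, set to values representative of the XRF / ICP-MS / AFS
method classes used for such surveys and configurable in the YAML.

## APCS-MLR

Metals are z-scored, checked with KMO and Bartlett tests (implemented from
the inverse correlation matrix), and decomposed by PCA of the correlation
matrix. Components are retained by the Kaiser rule (eigenvalue > 1) unless a
fixed count is requested, and varimax-rotated with Kaiser normalization by
default, since rotated sums of squared loadings are what such analyses
tabulate. Factor scores use the regression (Thurstone) method,
$S = Z R^{-1} \Lambda$ — the convention of the statistics packages this
workflow is usually run in. The **absolute** principal component score
shifts each score by that of an artificial sample with all concentrations
zero, whose standardized profile is $-\bar{C}_i/\sigma_i$; the zero sample
then scores exactly 0, giving non-centered source axes.

Each metal's *raw* concentration is regressed on the APCS columns
($C_i = b_0 + \sum_k b_k\,\mathrm{APCS}_k$); raw rather than standardized
is a deliberate choice so that $b_0$ has concentration units and can be
read as an unidentified-source term. The mean contribution of source $k$ to
metal $i$ is $b_k \overline{\mathrm{APCS}_k}$; the intercept is the
"unknown source". Mean contributions can be negative, so percent shares
normalize absolute values (rows then sum to 100) with signed means reported
alongside, and the overall share of a source is the unweighted mean of its
per-metal shares — a documented convention, since no standard aggregation
exists. Eigenvector sign indeterminacy is fixed by making each component's
largest-magnitude loading positive, so runs are bit-reproducible.

## PMF

PMF decomposes $X \approx GF$ with $G \ge 0$ (n × p contributions) and
$F \ge 0$ (p × m profiles) by minimizing

$$Q = \sum_{ij}\left(\frac{x_{ij} - \sum_k g_{jk} f_{ki}}{u_{ij}}\right)^2,$$

where $u_{ij}$ is the per-cell measurement uncertainty. Two published
uncertainty schemes are implemented; the default is the EPA-style one
($u = \frac{5}{6}\mathrm{MDL}$ below the detection limit, else
$\sqrt{(\sigma c)^2 + (0.5\,\mathrm{MDL})^2}$ with error fraction
$\sigma = 0.1$ by default, a value the field rarely prints), the alternative
the piecewise form $u = \mathrm{MDL}/3 + 0.2c$ ($c \le 3\,\mathrm{MDL}$),
$\mathrm{MDL}/3 + 0.1c$ above. Both substitute below-MDL concentrations by
MDL/2.

The solver uses multiplicative updates for weighted non-negative
factorization (weights $1/u^2$): monotone in $Q$, non-negativity preserved
exactly, and entirely adequate at survey scale. Twenty seeded random
restarts are fitted by default and the lowest-Q solution kept; convergence
is a relative $\Delta Q$ below $10^{-8}$ over ten consecutive iterations,
capped at 2000 iterations. The scale indeterminacy of $GF$ is fixed after
convergence by normalizing each profile row to sum 1 with $G$ absorbing the
scale. $Q_{robust}$ recomputes $Q$ with scaled residuals capped at
$|e/u| = 4$ (the receptor-modelling convention); a
$Q_{robust}/Q_{true}$ ratio of 1 means no outlier dominates. The
identifiability precondition $p(n+m) < nm$ is enforced.

The factor-number scan refits over a candidate range (conventionally 3–6),
reports the relative Q drop between consecutive p — the elbow criterion
practitioners read — and, per p, maps bootstrap refits (rows resampled with
replacement, the block-free choice appropriate when samples carry no serial
structure) onto base factors by maximum cosine similarity with a 0.6
acceptance threshold. Factor alignment for recovery checks uses exhaustive
permutation search, which is the exact optimal assignment at these factor
counts.

## Random-forest covariate screen

Each metal is regressed on eight covariates (pH, N, P, SOC continuous; soil
type, geological time, parent material, land use categorical, encoded as
integer codes — an encoding choice trees are insensitive to at these
cardinalities). Hyperparameters (mtry, minimum node size, tree count) are
chosen by random search (default budget 50) maximizing 5-fold
cross-validated predicted $R^2$, with bounds mtry 1–8, node size 1–20,
trees 300–2000. Importance is the permutation measure
$\%\Delta MSE = 100\,(MSE_{perm} - MSE_{base})/MSE_{base}$, computed by
permuting one covariate at a time *in held-out folds* — out-of-bag
importance is optimistic for correlated predictors, and the held-out
variant is the more defensible screen even though published workflows
rarely say which they used. Covariates at or above 15 % ΔMSE are flagged
(the boundary is included). Forest fits are delegated to `ranger` with a
fixed seed and one thread, so flags are reproducible.

For the repeated-run power check of the screen (100 seeded runs at
n = 1000) each run uses a fixed, sensible triple (3-fold CV, 300 trees)
rather than a fresh hyperparameter search: the search's own behaviour is
unit-tested separately, and the power check is about the importance
statistic, not the tuner.

## The synthetic generator

`generate_mixture()` draws p source profiles as flat-Dirichlet rows over
the panel (fixed after drawing), contributions as independent lognormal
columns with distinct per-source scales, and applies multiplicative
Gaussian noise $X = GF(1+\varepsilon)$ — matching the proportional term of
the uncertainty model — with negatives clipped to zero and counted (rare at
the ≤10 % noise levels used). Censoring pushes the lowest `censor_rate`
fraction of each metal below a per-metal MDL recorded in the truth object.
`generate_covariates()` plants covariate–source correlations of requested
strength (categoricals via quantile bins of a noisy copy of the log
contribution column). `simulate_survey()` draws per-metal truncated
lognormals whose parameters are calibrated, via closed-form
truncated-lognormal moments, so that the *truncated* distribution matches
the published mean/sd within the printed min/max; sampling is by inverse
CDF, so bounds are exact.

Study conditions used by the tests and the acceptance script (chosen once,
as the sizes a desk study of this kind would use): perfect-fit and
objective-monotonicity checks at n = 60–100; χ²-style calibration of
$Q/\mathrm{dof}$ at 5 % noise over 20 seeds at n = 100; profile recovery at
n = 500, p = 3, 2 % noise; the factor-count elbow on a 4-source mixture at
n = 200; APCS share recovery on a 2-source mixture at n = 1000; RF power
over 100 seeded runs at n = 1000.

What the generator does **not** emulate — and hence what green tests do not
show about real surveys: spatial autocorrelation (no variogram structure;
kriging is out of scope), inter-metal correlation beyond the mixture
structure, heavy-tailed analytical error, pH-dependent mobility, or any
geology. Recovery results here demonstrate correctness of the estimators
under their own assumptions, not field performance.

## Known limitations

* APCS-MLR's orthogonal, linear construction blurs composite sources;
  negative contribution means are handled by the absolute-value
  normalization, which is a convention, not a model.
* Multiplicative-update PMF can stall on plateaus; restarts mitigate but do
  not prove global optimality. No Fpeak-style rotational ambiguity tools
  and no DISP/BS-DISP error estimation are provided.
* The RF screen ranks associations; it does not identify sources, and
  correlated covariates split importance (a property the tests
  demonstrate deliberately).
* Reported overall source shares depend on documented aggregation
  conventions and should be compared across models, not read as physical
  mass fractions.
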