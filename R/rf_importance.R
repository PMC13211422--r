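# Per-metal random-forest regression on environmental covariates:
# hyperparameter search by cross-validated R^2, and permutation importance
# as %ΔMSE on held-out folds, with a screening threshold (default 15%).

#' Default covariate list for the factor screen
#' @return Character vector: pH, N, P, SOC, soil_type, geological_time,
#'   parent_material, land_use.
#' @export
default_covariates <- function() {
  c("pH", "N", "P", "SOC", "soil_type", "geological_time",
    "parent_material", "land_use")
}

#' Random-forest run specification
#'
#' @param covariates Covariate column names to use as predictors.
#' @param mtry,nodesize,ntree Search-space bounds (inclusive integer
#'   ranges) bracketing typical optima for this problem size.
#' @param folds Cross-validation folds.
#' @param budget Random-search candidates evaluated.
#' @param seed Integer seed.
#' @return An `rf_spec` list.
#' @export
rf_spec <- function(covariates = default_covariates(),
                    mtry = c(1, length(covariates)),
                    nodesize = c(1, 20), ntree = c(300, 2000),
                    folds = 5, budget = 50, seed = 1) {
  stopifnot(folds >= 2, ntree[1] >= 100)
  structure(list(covariates = covariates, mtry = mtry, nodesize = nodesize,
                 ntree = ntree, folds = folds, budget = budget, seed = seed),
            class = "rf_spec")
}

# Encode covariates for tree models: categoricals as integer codes.
.encode_covariates <- function(samples, covariates) {
  df <- as.data.frame(samples)
  missing <- setdiff(covariates, names(df))
  if (length(missing) > 0) {
    stop("covariate(s) not in table: ", paste(missing, collapse = ", "))
  }
  enc <- lapply(covariates, function(v) {
    x <- df[[v]]
    if (is.numeric(x)) return(x)
    f <- factor(x)
    if (nlevels(f) < 2) return(NULL)
    as.integer(f)
  })
  names(enc) <- covariates
  dropped <- covariates[vapply(enc, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("single-level covariate(s) dropped: ",
            paste(dropped, collapse = ", "))
    enc <- enc[!vapply(enc, is.null, logical(1))]
  }
  as.data.frame(enc)
}

.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  split(sample.int(n), rep_len(seq_len(k), n))
}

.ranger_fit <- function(df, mtry, nodesize, ntree, seed) {
  ranger::ranger(y ~ ., data = df, num.trees = ntree, mtry = mtry,
                 min.node.size = nodesize, seed = seed, num.threads = 1,
                 verbose = FALSE)
}

.cv_r2 <- function(dat, mtry, nodesize, ntree, folds, seed) {
  preds <- rep(NA_real_, nrow(dat))
  for (i in seq_along(folds)) {
    test <- folds[[i]]
    fit <- .ranger_fit(dat[-test, , drop = FALSE], mtry, nodesize, ntree,
                       seed = seed + i)
    preds[test] <- stats::predict(fit, dat[test, , drop = FALSE])$predictions
  }
  1 - mean((dat$y - preds)^2) / stats::var(dat$y)
}

#' Fit a per-metal random forest with hyperparameter search
#'
#' Random search over (mtry, nodesize, ntree) maximizing k-fold
#' cross-validated predicted R^2, then a final refit on all data with the
#' best triple. Deterministic given the spec's seed. An mtry bound above
#' the encoded predictor count is clipped with a warning; single-level
#' categorical covariates are dropped with a warning.
#'
#' @param samples A [sample_table()] with covariate columns.
#' @param metal Response metal name.
#' @param spec An [rf_spec()].
#' @return An `rf_fit` list: `model` (ranger forest), `best`
#'   (mtry/nodesize/ntree), `predicted_r2` (CV), `data` (encoded design),
#'   `folds`, `spec`, `metal`.
#' @export
fit_rf <- function(samples, metal, spec = rf_spec()) {
  if (!metal %in% names(samples)) stop("metal not in table: ", metal)
  y <- samples[[metal]]
  Xc <- .encode_covariates(samples, spec$covariates)
  if (nrow(Xc) < 50) stop("need at least 50 samples")
  p <- ncol(Xc)
  mtry_hi <- spec$mtry[2]
  if (mtry_hi > p) {
    warning("mtry upper bound clipped to number of predictors (", p, ")")
    mtry_hi <- p
  }
  dat <- cbind(y = y, Xc)
  folds <- .cv_folds(nrow(dat), spec$folds, seed = spec$seed)

  set.seed(spec$seed)
  cand <- data.frame(
    mtry = sample(spec$mtry[1]:mtry_hi, spec$budget, replace = TRUE),
    nodesize = sample(spec$nodesize[1]:spec$nodesize[2], spec$budget,
                      replace = TRUE),
    ntree = sample(spec$ntree[1]:spec$ntree[2], spec$budget, replace = TRUE)
  )
  cand <- unique(cand)
  r2 <- vapply(seq_len(nrow(cand)), function(i) {
    .cv_r2(dat, cand$mtry[i], cand$nodesize[i], cand$ntree[i], folds,
           seed = spec$seed + 1000 * i)
  }, numeric(1))
  best <- cand[which.max(r2), ]
  model <- .ranger_fit(dat, best$mtry, best$nodesize, best$ntree,
                       seed = spec$seed)
  structure(list(model = model, best = best, predicted_r2 = max(r2),
                 data = dat, folds = folds, spec = spec, metal = metal),
            class = "rf_fit")
}

#' Permutation importance as percent MSE increase
#'
#' For each covariate, refits the forest on each training fold, permutes
#' that covariate in the held-out fold and reports
#' `%ΔMSE = 100 * (MSE_permuted - MSE_base) / MSE_base`, averaged over
#' `n_repeats` permutations and all folds. Held-out (not in-bag)
#' evaluation avoids optimism for correlated predictors.
#'
#' @param fit An [fit_rf()] result.
#' @param n_repeats Permutations per covariate per fold.
#' @param seed Integer seed.
#' @return Data frame: `covariate`, `pct_delta_mse`, `spread` (sd over
#'   fold-by-repeat values).
#' @export
permutation_importance <- function(fit, n_repeats = 5, seed = 1) {
  dat <- fit$data
  covs <- setdiff(names(dat), "y")
  vals <- matrix(0, nrow = length(covs),
                 ncol = length(fit$folds) * n_repeats,
                 dimnames = list(covs, NULL))
  col <- 0L
  for (i in seq_along(fit$folds)) {
    test <- fit$folds[[i]]
    fold_fit <- .ranger_fit(dat[-test, , drop = FALSE], fit$best$mtry,
                            fit$best$nodesize, fit$best$ntree,
                            seed = fit$spec$seed + i)
    test_dat <- dat[test, , drop = FALSE]
    base_pred <- stats::predict(fold_fit, test_dat)$predictions
    mse_base <- mean((test_dat$y - base_pred)^2)
    for (r in seq_len(n_repeats)) {
      col <- col + 1L
      for (v in covs) {
        set.seed(seed + 7919 * col + match(v, covs))
        perm_dat <- test_dat
        perm_dat[[v]] <- sample(perm_dat[[v]])
        perm_pred <- stats::predict(fold_fit, perm_dat)$predictions
        mse_perm <- mean((test_dat$y - perm_pred)^2)
        vals[v, col] <- 100 * (mse_perm - mse_base) / mse_base
      }
    }
  }
  data.frame(covariate = covs,
             pct_delta_mse = rowMeans(vals),
             spread = apply(vals, 1, stats::sd),
             stringsAsFactors = FALSE)
}

#' Screen covariates by the importance threshold
#'
#' Covariates whose permutation importance meets or exceeds the threshold
#' (default 15 percent MSE increase) are flagged as important drivers of
#' the metal. The boundary value is included (>=).
#'
#' @param importance A [permutation_importance()] data frame.
#' @param threshold Percent ΔMSE cut, default 15.
#' @return Character vector of flagged covariates.
#' @export
important_factors <- function(importance, threshold = 15) {
  importance$covariate[importance$pct_delta_mse >= threshold]
}

#' Run the factor screen for every panel metal
#'
#' Convenience wrapper: [fit_rf()], [permutation_importance()] and
#' [important_factors()] per metal.
#'
#' @param samples A [sample_table()] with covariates.
#' @param spec An [rf_spec()].
#' @param n_repeats Permutations per covariate per fold.
#' @param threshold Importance cut (percent ΔMSE).
#' @return List per metal: `best`, `predicted_r2`, `importance`, `flagged`.
#' @export
rf_screen <- function(samples, spec = rf_spec(), n_repeats = 5,
                      threshold = 15) {
  out <- lapply(metals(samples), function(m) {
    sp <- spec
    sp$seed <- spec$seed + match(m, metals(samples))
    fit <- fit_rf(samples, m, sp)
    imp <- permutation_importance(fit, n_repeats = n_repeats, seed = sp$seed)
    list(metal = m, best = fit$best, predicted_r2 = fit$predicted_r2,
         importance = imp, flagged = important_factors(imp, threshold))
  })
  stats::setNames(out, metals(samples))
}
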