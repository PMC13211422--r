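# APCS-MLR source apportionment: z-score standardization, PCA of the
# correlation matrix with varimax rotation, absolute principal component
# scores (factor scores shifted by the score of an artificial
# zero-concentration sample), and per-metal OLS of raw concentrations on the
# APCS columns to split each metal between identified sources and an
# "unknown source" intercept.

#' Z-score standardize the metal panel
#'
#' `Z = (C - mean) / sd`, per metal.
#'
#' @param samples A [sample_table()] (or a numeric matrix).
#' @return List: `Z` (n x m matrix, column means 0 and sds 1), `mean`, `sd`
#'   (named per-metal vectors).
#' @export
standardize_metals <- function(samples) {
  X <- if (inherits(samples, "sample_table")) conc_matrix(samples) else as.matrix(samples)
  if (nrow(X) < 3) stop("need at least 3 samples")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv == 0)) {
    stop("zero-variance metal(s): ",
         paste(colnames(X)[sdv == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  list(Z = Z, mean = mu, sd = sdv)
}

#' KMO sampling adequacy and Bartlett's sphericity test
#'
#' The Kaiser-Meyer-Olkin measure compares simple correlations with partial
#' correlations from the inverse correlation matrix; Bartlett's test checks
#' the correlation matrix against the identity with
#' `chi2 = -((n-1) - (2m+5)/6) * log det(R)` on `m(m-1)/2` degrees of
#' freedom.
#'
#' @param samples A [sample_table()] or numeric matrix.
#' @return List: `kmo` in `[0, 1]`, `bartlett_chisq`, `bartlett_df`,
#'   `bartlett_p`.
#' @export
kmo_bartlett <- function(samples) {
  X <- if (inherits(samples, "sample_table")) conc_matrix(samples) else as.matrix(samples)
  n <- nrow(X); m <- ncol(X)
  if (n <= m) stop("need more samples than metals")
  R <- stats::cor(X)
  if (rcond(R) < 1e-12)
    stop("correlation matrix is singular (collinear metals)")
  Ri <- solve(R)
  D <- diag(1 / sqrt(diag(Ri)))
  P <- -D %*% Ri %*% D  # partial correlations
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(P[off]^2))
  detR <- det(R)
  if (detR <= 0) stop("correlation matrix is singular (collinear metals)")
  chisq <- -((n - 1) - (2 * m + 5) / 6) * log(detR)
  df <- m * (m - 1) / 2
  list(kmo = kmo, bartlett_chisq = chisq, bartlett_df = df,
       bartlett_p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Principal component extraction with optional varimax rotation
#'
#' Eigendecomposition of the metal correlation matrix. Components are
#' retained by the Kaiser criterion (eigenvalue > 1) or a fixed count;
#' loadings are eigenvectors scaled by sqrt(eigenvalue), optionally
#' varimax-rotated with Kaiser normalization. Each component's
#' largest-|loading| entry is made positive so runs are reproducible despite
#' eigenvector sign indeterminacy.
#'
#' @param Z Standardized matrix from [standardize_metals()].
#' @param retention `"kaiser"` or `"fixed"`.
#' @param k Number of components when `retention = "fixed"`.
#' @param rotate `"varimax"` or `"none"`.
#' @return List: `eigenvalues`, `variance_pct`, `cumulative_pct` (initial
#'   solution), `loadings` (m x k, rotated if requested), `rotated_ssq`
#'   (sums of squared loadings after rotation), `rotation` (k x k matrix),
#'   `k`, `cor` (the correlation matrix).
#' @export
pca_extract <- function(Z, retention = c("kaiser", "fixed"), k = NULL,
                        rotate = c("varimax", "none")) {
  retention <- match.arg(retention)
  rotate <- match.arg(rotate)
  R <- stats::cor(Z)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  m <- ncol(R)
  if (retention == "kaiser") {
    k <- sum(ev > 1)
    if (k == 0) stop("no eigenvalue exceeds 1; use retention = \"fixed\"")
  } else {
    stopifnot(!is.null(k), k >= 1, k <= m)
  }
  L <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rot <- diag(k)
  if (rotate == "varimax" && k > 1) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- unclass(vm$loadings)
    rot <- vm$rotmat
  }
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(L[, j]))
    if (L[i_max, j] < 0) {
      L[, j] <- -L[, j]
      rot[, j] <- -rot[, j]
    }
  }
  dimnames(L) <- list(colnames(R), paste0("PC", seq_len(k)))
  list(eigenvalues = ev,
       variance_pct = 100 * ev / m,
       cumulative_pct = cumsum(100 * ev / m),
       loadings = L,
       rotated_ssq = colSums(L^2),
       rotation = rot, k = k, cor = R)
}

#' Absolute principal component scores
#'
#' Factor scores by the regression (Thurstone) method,
#' `S = Z %*% solve(R) %*% L`, shifted by the score of an artificial sample
#' whose every concentration is zero (standardized value `-mean/sd` per
#' metal): `APCS_k = S_k(sample) - S_k(z0)`. The zero sample itself thus
#' scores exactly 0 on every factor, giving non-centered source axes
#' suitable for regression.
#'
#' @param pca A [pca_extract()] result.
#' @param Z Standardized matrix the PCA was built from.
#' @param col_moments List with `mean` and `sd` per metal (from
#'   [standardize_metals()]).
#' @return n x k matrix of APCS scores.
#' @export
apcs_scores <- function(pca, Z, col_moments) {
  W <- solve(pca$cor, pca$loadings)      # score coefficient matrix
  scores <- Z %*% W
  z0 <- matrix(-col_moments$mean / col_moments$sd, nrow = 1)
  s0 <- z0 %*% W
  sweep(scores, 2, as.numeric(s0), "-")
}

#' Regress metals on APCS scores and apportion sources
#'
#' Ordinary least squares of each metal's raw concentration (mg/kg) on the
#' APCS columns: `C_i = b0 + sum_k b_k * APCS_k`. The mean contribution of
#' identified source k to metal i is `b_k * mean(APCS_k)`; the intercept
#' `b0` is the "unknown source". Percent shares divide absolute mean
#' contributions so they are positive and sum to 100 per metal; signed
#' means are also reported. The overall share of each source is the
#' unweighted mean of its per-metal shares.
#'
#' @param samples A [sample_table()] (raw concentrations).
#' @param apcs n x k APCS matrix from [apcs_scores()].
#' @return An `apcs_model` list: `coefficients` (per metal: b0, b_k,
#'   adjusted R-squared, F-test p), `contributions` (signed per-metal mean
#'   contribution per source incl. unknown), `shares` (per-metal percent,
#'   rows sum to 100), `overall_shares`.
#' @export
mlr_apportion <- function(samples, apcs) {
  X <- if (inherits(samples, "sample_table")) conc_matrix(samples) else as.matrix(samples)
  k <- ncol(apcs)
  if (nrow(X) <= k + 1) stop("need n > k + 1 samples")
  if (qr(cbind(1, apcs))$rank < k + 1) stop("APCS design is rank deficient")
  apcs_means <- colMeans(apcs)
  src_names <- c(paste0("factor", seq_len(k)), "unknown")

  fit_one <- function(y) {
    fit <- stats::lm(y ~ apcs)
    # summary.lm warns on exact fits; those are legitimate here
    sm <- suppressWarnings(summary(fit))
    b <- unname(stats::coef(fit))
    fp <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    contrib <- c(b[-1] * apcs_means, b[1])
    list(b = b, adj_r2 = sm$adj.r.squared, f_p = unname(fp), contrib = contrib)
  }
  fits <- lapply(seq_len(ncol(X)), function(i) fit_one(X[, i]))

  coefficients <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(metal = colnames(X)[i],
               t(stats::setNames(f$b, c("b0", paste0("b", seq_len(k))))),
               adj_r2 = f$adj_r2, f_p = f$f_p,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  contributions <- t(vapply(fits, function(f) f$contrib, numeric(k + 1)))
  dimnames(contributions) <- list(colnames(X), src_names)
  abs_c <- abs(contributions)
  shares <- 100 * abs_c / rowSums(abs_c)
  overall <- colMeans(shares)
  structure(list(coefficients = coefficients, contributions = contributions,
                 shares = shares, overall_shares = overall, k = k),
            class = "apcs_model")
}

#' Run the full APCS-MLR chain
#'
#' Standardization, adequacy tests, PCA with rotation, APCS scoring and
#' per-metal apportionment in one call.
#'
#' @inheritParams standardize_metals
#' @inheritParams pca_extract
#' @return List: `adequacy` ([kmo_bartlett()]), `pca`, `apcs`, `model`
#'   ([mlr_apportion()] result), `moments`.
#' @export
apcs_mlr <- function(samples, retention = "kaiser", k = NULL,
                     rotate = "varimax") {
  std <- standardize_metals(samples)
  adequacy <- kmo_bartlett(std$Z)
  pca <- pca_extract(std$Z, retention = retention, k = k, rotate = rotate)
  apcs <- apcs_scores(pca, std$Z, std)
  model <- mlr_apportion(samples, apcs)
  list(adequacy = adequacy, pca = pca, apcs = apcs, model = model,
       moments = std)
}

#' Write APCS-MLR outputs
#'
#' Variance-explained, per-metal coefficient/diagnostic and share tables as
#' CSV plus a JSON model card.
#'
#' @param result An [apcs_mlr()] result.
#' @param dir Output directory.
#' @param seed Seed recorded in the model card (the chain is deterministic).
#' @return Written paths, invisibly.
#' @export
write_apcs_report <- function(result, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ve <- data.frame(component = seq_along(result$pca$eigenvalues),
                   eigenvalue = result$pca$eigenvalues,
                   variance_pct = result$pca$variance_pct,
                   cumulative_pct = result$pca$cumulative_pct)
  paths <- c(variance = file.path(dir, "apcs_variance_explained.csv"),
             coef = file.path(dir, "apcs_coefficients.csv"),
             shares = file.path(dir, "apcs_shares.csv"),
             card = file.path(dir, "apcs_model_card.json"))
  utils::write.csv(ve, paths["variance"], row.names = FALSE)
  utils::write.csv(result$model$coefficients, paths["coef"], row.names = FALSE)
  utils::write.csv(data.frame(metal = rownames(result$model$shares),
                              result$model$shares, check.names = FALSE),
                   paths["shares"], row.names = FALSE)
  jsonlite::write_json(list(k = result$pca$k, kmo = result$adequacy$kmo,
                            bartlett_p = result$adequacy$bartlett_p,
                            overall_shares = as.list(result$model$overall_shares),
                            share_normalization = "absolute mean contributions",
                            seed = seed),
                       paths["card"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
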