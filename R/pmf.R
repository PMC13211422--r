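# Positive matrix factorization: X (n samples x m metals) ~ G F with
# G >= 0 (source contributions) and F >= 0 (source profiles), fitted by
# minimizing the uncertainty-weighted objective
#   Q = sum_ij ((x_ij - [GF]_ij) / u_ij)^2
# with multiplicative updates for weighted non-negative factorization.

#' Build a measurement-uncertainty matrix
#'
#' Two published uncertainty schemes for receptor modelling:
#' \describe{
#'   \item{epa}{below MDL: `u = 5/6 * MDL`; otherwise
#'     `u = sqrt((sigma * c)^2 + (0.5 * MDL)^2)` with error fraction
#'     `sigma`.}
#'   \item{piecewise}{`u = MDL/3 + 0.2 * c` for `c <= 3 * MDL`, else
#'     `u = MDL/3 + 0.1 * c`.}
#' }
#' Both substitute below-MDL concentrations by `MDL / 2` in the returned
#' concentration matrix.
#'
#' @param samples A [sample_table()] or numeric concentration matrix.
#' @param ref A [read_reference()] set supplying per-metal MDLs (or a named
#'   numeric vector of MDLs).
#' @param scheme `"epa"` or `"piecewise"`.
#' @param error_fraction The epa scheme's proportional error fraction, in
#'   (0, 1). Default 0.1.
#' @return List: `U` (uncertainties, same shape as the data, all > 0), `X`
#'   (concentrations with below-MDL substitution), `below_mdl` (logical
#'   mask), `scheme`, `error_fraction`, `mdl`.
#' @export
build_uncertainty <- function(samples, ref, scheme = c("epa", "piecewise"),
                              error_fraction = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(error_fraction > 0, error_fraction < 1)
  X <- if (inherits(samples, "sample_table")) conc_matrix(samples) else as.matrix(samples)
  mdl <- if (is.list(ref)) ref$mdl else ref
  mdl <- mdl[colnames(X)]
  if (anyNA(mdl)) {
    stop("MDL missing for: ", paste(colnames(X)[is.na(mdl)], collapse = ", "))
  }
  M <- matrix(mdl, nrow = nrow(X), ncol = ncol(X), byrow = TRUE)
  below <- X <= M
  U <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  if (scheme == "epa") {
    U[below] <- (5 / 6) * M[below]
    U[!below] <- sqrt((error_fraction * X[!below])^2 + (0.5 * M[!below])^2)
  } else {
    low <- X <= 3 * M
    U[low] <- M[low] / 3 + 0.2 * X[low]
    U[!low] <- M[!low] / 3 + 0.1 * X[!low]
  }
  Xs <- X
  Xs[below] <- M[below] / 2
  list(U = U, X = Xs, below_mdl = below, scheme = scheme,
       error_fraction = error_fraction, mdl = mdl)
}

.q_value <- function(X, U, G, F) sum(((X - G %*% F) / U)^2)

#' Fit a positive matrix factorization
#'
#' Minimizes the uncertainty-weighted least-squares objective by
#' multiplicative updates (weights `1/u^2`), which keep `G` and `F`
#' non-negative and never increase Q. The best of `restarts` seeded random
#' initializations is returned. After convergence each profile row of `F`
#' is normalized to sum 1, with `G` absorbing the scale, so `G F` is
#' unchanged.
#'
#' @param X Non-negative concentration matrix (n x m), below-MDL cells
#'   already substituted.
#' @param U Positive uncertainty matrix of the same shape (or a
#'   [build_uncertainty()] result, supplying both `X` and `U`).
#' @param p Number of factors, with `p * (n + m) < n * m` for
#'   identifiability.
#' @param restarts Random initializations; the lowest-Q fit is kept.
#' @param seed Integer seed; restart r uses `seed + r`.
#' @param tol Convergence: relative change in Q below `tol` over 10
#'   consecutive iterations.
#' @param max_iter Iteration cap per restart.
#' @return A `pmf_fit` list: `G` (n x p), `F` (p x m, rows sum to 1),
#'   `residuals`, `Q_true`, `Q_robust`, `converged`, `iterations`,
#'   `restart` (index of winning start), `seed`, `Q_trace` of the winning
#'   start.
#' @export
pmf_fit <- function(X, U, p, restarts = 20, seed = 1, tol = 1e-8,
                    max_iter = 2000) {
  if (is.list(U) && !is.null(U$U)) {
    X <- U$X
    U <- U$U
  }
  X <- as.matrix(X); U <- as.matrix(U)
  n <- nrow(X); m <- ncol(X)
  stopifnot(all(X >= 0), all(U > 0), p >= 1)
  if (p * (n + m) >= n * m) {
    stop("p = ", p, " too large for identifiability: need p*(n+m) < n*m")
  }
  W <- 1 / U^2
  WX <- W * X
  eps <- .Machine$double.eps
  scale0 <- sqrt(mean(X) / p)

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    G <- matrix(stats::runif(n * p, 0.1, 1) * scale0, n, p)
    F <- matrix(stats::runif(p * m, 0.1, 1) * scale0, p, m)
    q_prev <- .q_value(X, U, G, F)
    trace <- q_prev
    stable <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      GF <- G %*% F
      G <- G * (WX %*% t(F)) / ((W * GF) %*% t(F) + eps)
      GF <- G %*% F
      F <- F * (t(G) %*% WX) / (t(G) %*% (W * GF) + eps)
      q <- .q_value(X, U, G, F)
      trace <- c(trace, q)
      rel <- abs(q_prev - q) / max(q_prev, eps)
      stable <- if (rel < tol) stable + 1L else 0L
      q_prev <- q
      if (stable >= 10L) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || q_prev < best$Q_true) {
      best <- list(G = G, F = F, Q_true = q_prev, converged = converged,
                   iterations = it, restart = r, Q_trace = trace)
    }
  }

  # fix scale indeterminacy: profile rows sum to 1, G absorbs scale
  s <- rowSums(best$F)
  s[s == 0] <- 1
  F <- best$F / s
  G <- best$G * rep(s, each = n)
  E <- X - G %*% F
  qs <- q_values_from(E, U)
  structure(list(G = G, F = F, residuals = E,
                 Q_true = qs[["q_true"]], Q_robust = qs[["q_robust"]],
                 converged = best$converged, iterations = best$iterations,
                 restart = best$restart, seed = seed,
                 Q_trace = best$Q_trace, X = X, U = U),
            class = "pmf_fit")
}

q_values_from <- function(E, U, cap = 4) {
  r <- E / U
  rc <- pmin(pmax(r, -cap), cap)
  c(q_true = sum(r^2), q_robust = sum(rc^2))
}

#' Q diagnostics of a PMF fit
#'
#' `Q_true` is the weighted objective; `Q_robust` recomputes it with scaled
#' residuals `|e/u| > 4` capped at 4 (the receptor-modelling convention), so
#' `Q_robust <= Q_true` and a ratio near 1 indicates no outlier dominance.
#'
#' @param model A [pmf_fit()] result.
#' @param cap Scaled-residual cap, default 4.
#' @return Named list `q_true`, `q_robust`, `ratio`.
#' @export
q_values <- function(model, cap = 4) {
  qs <- q_values_from(model$residuals, model$U, cap = cap)
  list(q_true = qs[["q_true"]], q_robust = qs[["q_robust"]],
       ratio = if (qs[["q_true"]] > 0) qs[["q_robust"]] / qs[["q_true"]] else 1)
}

#' Per-metal and overall factor contributions
#'
#' The share of factor k in metal i is the mean over samples of
#' `g_jk * f_ki` divided by the total across factors; the overall share of
#' factor k is its mean apportioned mass across all metals over the total
#' mass.
#'
#' @param model A [pmf_fit()] result.
#' @return List: `metal_shares` (m x p percent matrix, rows sum to 100;
#'   all-zero metals give `NA` rows with a warning), `overall_shares`
#'   (length p, sums to 100).
#' @export
pmf_contributions <- function(model) {
  G <- model$G; F <- model$F
  p <- ncol(G); m <- ncol(F)
  # mean apportioned mass of factor k in metal i: mean_j g_jk * f_ki
  mass <- t(F) * rep(colMeans(G), each = m)   # m x p
  tot <- rowSums(mass)
  shares <- 100 * mass / tot
  if (any(tot == 0)) {
    warning("metal(s) with zero apportioned mass: ",
            paste(colnames(model$X)[tot == 0], collapse = ", "))
    shares[tot == 0, ] <- NA_real_
  }
  dimnames(shares) <- list(colnames(model$X), paste0("factor", seq_len(p)))
  overall <- 100 * colSums(mass) / sum(mass)
  names(overall) <- paste0("factor", seq_len(p))
  list(metal_shares = shares, overall_shares = overall)
}

# all permutations of 1..k (k <= 7 in practice)
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Align two profile matrices by optimal factor assignment
#'
#' Finds the one-to-one matching of rows of `F_hat` to rows of `F_true`
#' maximizing total cosine similarity (exhaustive over permutations, exact
#' for the factor counts used here).
#'
#' @param F_hat,F_true p x m profile matrices.
#' @return List: `perm` (row of `F_hat` matched to each row of `F_true`),
#'   `cosines` (per matched pair), `mean_cosine`.
#' @export
align_profiles <- function(F_hat, F_true) {
  p <- nrow(F_true)
  stopifnot(nrow(F_hat) == p)
  C <- outer(seq_len(p), seq_len(p),
             Vectorize(function(i, j) .cosine(F_true[i, ], F_hat[j, ])))
  perms <- .permutations(p)
  scores <- apply(perms, 1, function(pm) sum(C[cbind(seq_len(p), pm)]))
  best <- perms[which.max(scores), ]
  cosines <- C[cbind(seq_len(p), best)]
  list(perm = best, cosines = cosines, mean_cosine = mean(cosines))
}

#' Scan factor numbers with bootstrap factor mapping
#'
#' Refits the factorization for each candidate factor count, reporting
#' `Q_true`, `Q_robust`, their ratio, and the relative Q drop from the
#' previous p. For each p, bootstrap resamples of the rows (samples) are
#' refitted and each bootstrap factor mapped to the base factor of maximum
#' cosine similarity; a mapping counts only when that similarity reaches
#' `map_threshold` (default 0.6). Candidate p violating the identifiability
#' bound are skipped with a warning.
#'
#' @param X,U Concentration and uncertainty matrices (or a
#'   [build_uncertainty()] result as `U`).
#' @param p_range Integer candidates, e.g. `3:6`.
#' @param bootstrap_n Bootstrap resamples per p (0 to skip).
#' @param seed Integer seed.
#' @param restarts,max_iter Passed to [pmf_fit()] (bootstrap refits use
#'   fewer restarts).
#' @param map_threshold Minimum cosine for a bootstrap factor to map.
#' @return List: `summary` (data frame per p: q_true, q_robust, ratio,
#'   rel_q_drop), `mapping` (per p, percent of bootstrap runs in which each
#'   base factor was mapped), `fits` (the base `pmf_fit` per p).
#' @export
scan_factors <- function(X, U, p_range = 3:6, bootstrap_n = 100, seed = 1,
                         restarts = 10, max_iter = 2000, map_threshold = 0.6) {
  if (is.list(U) && !is.null(U$U)) {
    X <- U$X
    U <- U$U
  }
  n <- nrow(X); m <- ncol(X)
  ok <- vapply(p_range, function(p) p * (n + m) < n * m, logical(1))
  if (any(!ok)) {
    warning("skipping p = ", paste(p_range[!ok], collapse = ", "),
            " (identifiability bound)")
    p_range <- p_range[ok]
  }
  fits <- list(); mapping <- list(); rows <- list()
  q_prev <- NA_real_
  for (p in p_range) {
    fit <- pmf_fit(X, U, p, restarts = restarts, seed = seed + 100 * p,
                   max_iter = max_iter)
    qd <- q_values(fit)
    rows[[as.character(p)]] <- data.frame(
      p = p, q_true = qd$q_true, q_robust = qd$q_robust, ratio = qd$ratio,
      rel_q_drop = if (is.na(q_prev)) NA_real_ else (q_prev - qd$q_true) / q_prev)
    q_prev <- qd$q_true
    fits[[as.character(p)]] <- fit

    if (bootstrap_n > 0) {
      hit <- integer(p)
      for (b in seq_len(bootstrap_n)) {
        set.seed(seed + 1000 * p + b)
        idx <- sample.int(n, n, replace = TRUE)
        bfit <- pmf_fit(X[idx, , drop = FALSE], U[idx, , drop = FALSE], p,
                        restarts = 2, seed = seed + 1000 * p + b,
                        max_iter = max_iter)
        for (k in seq_len(p)) {
          cs <- vapply(seq_len(p), function(j)
            .cosine(bfit$F[k, ], fit$F[j, ]), numeric(1))
          j_best <- which.max(cs)
          if (cs[j_best] >= map_threshold) hit[j_best] <- hit[j_best] + 1L
        }
      }
      mapping[[as.character(p)]] <- 100 * hit / bootstrap_n
    }
  }
  list(summary = do.call(rbind, rows), mapping = mapping, fits = fits)
}

#' Write PMF outputs
#'
#' G, F, residual and scaled-residual matrices as CSV plus a JSON
#' diagnostics file.
#'
#' @param model A [pmf_fit()] result.
#' @param dir Output directory.
#' @return Written paths, invisibly.
#' @export
write_pmf_report <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(G = file.path(dir, "pmf_contributions_G.csv"),
             F = file.path(dir, "pmf_profiles_F.csv"),
             resid = file.path(dir, "pmf_residuals.csv"),
             scaled = file.path(dir, "pmf_scaled_residuals.csv"),
             diag = file.path(dir, "pmf_diagnostics.json"))
  utils::write.csv(model$G, paths["G"], row.names = FALSE)
  utils::write.csv(model$F, paths["F"], row.names = FALSE)
  utils::write.csv(model$residuals, paths["resid"], row.names = FALSE)
  utils::write.csv(model$residuals / model$U, paths["scaled"], row.names = FALSE)
  qd <- q_values(model)
  jsonlite::write_json(list(q_true = qd$q_true, q_robust = qd$q_robust,
                            ratio = qd$ratio, converged = model$converged,
                            iterations = model$iterations,
                            restart = model$restart, seed = model$seed),
                       paths["diag"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
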