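test_that("standardization gives identity column moments", {
  st <- random_table(50, seed = 20)
  std <- standardize_metals(st)
  expect_equal(unname(colMeans(std$Z)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(std$Z, 2, sd)), rep(1, 8), tolerance = 1e-10)
  # a cell one sd above the mean standardizes to 1 (printed Pb moments)
  expect_equal((36.04 - 25.01) / 11.03, 1, tolerance = 1e-12)
  df <- as.data.frame(st)
  df$Cu <- 5
  expect_error(standardize_metals(sample_table(df)), "Cu")
})

test_that("KMO and Bartlett behave as expected under known structure", {
  set.seed(21)
  # independent columns: Bartlett should not reject, KMO near 1/2
  Z0 <- matrix(rnorm(2000 * 8), 2000, 8)
  colnames(Z0) <- default_panel()
  r0 <- kmo_bartlett(Z0)
  expect_gt(r0$bartlett_p, 0.01)
  expect_equal(r0$kmo, 0.5, tolerance = 0.1)
  # one planted common factor: strong structure, small p, KMO > 0.6
  f <- rnorm(2000)
  Z1 <- sapply(1:8, function(j) 0.8 * f + 0.6 * rnorm(2000))
  colnames(Z1) <- default_panel()
  r1 <- kmo_bartlett(Z1)
  expect_lt(r1$bartlett_p, 1e-10)
  expect_gt(r1$kmo, 0.6)
  # perfectly collinear pair is singular
  Zc <- Z0
  Zc[, 2] <- 2 * Zc[, 1]
  expect_error(kmo_bartlett(Zc), "singular")
})

test_that("PCA eigenstructure matches closed forms", {
  set.seed(22)
  # near-identity correlation: all eigenvalues close to 1, trace exactly 8
  Z <- matrix(rnorm(5000 * 8), 5000, 8)
  colnames(Z) <- default_panel()
  p0 <- pca_extract(Z, retention = "fixed", k = 2, rotate = "none")
  expect_equal(sum(p0$eigenvalues), 8, tolerance = 1e-8)
  expect_true(all(abs(p0$eigenvalues - 1) < 0.15))
  # rank-1 equicorrelation: loading 0.9 factor gives lead eigenvalue
  # 1 + 7 * 0.81 and the rest 0.19
  R <- matrix(0.81, 8, 8)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 1 + 7 * 0.81, tolerance = 1e-10)
  f <- rnorm(20000)
  Z1 <- sapply(1:8, function(j) 0.9 * f + sqrt(1 - 0.81) * rnorm(20000))
  colnames(Z1) <- default_panel()
  p1 <- pca_extract(scale(Z1), retention = "kaiser", rotate = "none")
  expect_equal(p1$k, 1)
  expect_equal(p1$eigenvalues[1], 6.67, tolerance = 0.15)
})

test_that("varimax rotation preserves communalities and cumulative variance", {
  mix <- generate_mixture(300, p = 3, noise_sd = 0.05, seed = 23)
  std <- standardize_metals(mix$samples)
  un <- pca_extract(std$Z, retention = "fixed", k = 3, rotate = "none")
  ro <- pca_extract(std$Z, retention = "fixed", k = 3, rotate = "varimax")
  expect_equal(rowSums(un$loadings^2), rowSums(ro$loadings^2), tolerance = 1e-8)
  expect_equal(sum(un$rotated_ssq), sum(ro$rotated_ssq), tolerance = 1e-8)
  expect_true(all(diff(ro$cumulative_pct) >= -1e-12))
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(3)) {
    expect_gt(ro$loadings[which.max(abs(ro$loadings[, j])), j], 0)
  }
})

test_that("APCS of the zero-concentration pseudo-sample is exactly zero", {
  mix <- generate_mixture(200, p = 3, noise_sd = 0.05, seed = 24)
  std <- standardize_metals(mix$samples)
  pca <- pca_extract(std$Z, retention = "fixed", k = 3)
  z0 <- matrix(-std$mean / std$sd, nrow = 1)
  colnames(z0) <- colnames(std$Z)
  apcs0 <- apcs_scores(pca, z0, std)
  expect_equal(unname(as.numeric(apcs0)), rep(0, 3), tolerance = 1e-10)
  # printed Pb moments give the expected standardized zero-sample entry
  expect_equal(-25.01 / 11.03, -2.2675, tolerance = 1e-4)
})

test_that("APCS differences between samples are shift invariant", {
  mix <- generate_mixture(20, p = 2, noise_sd = 0.05, seed = 25)
  X <- conc_matrix(mix$samples)
  run <- function(M) {
    st <- sample_table(as.data.frame(M))
    std <- standardize_metals(st)
    pca <- pca_extract(std$Z, retention = "fixed", k = 2, rotate = "none")
    apcs_scores(pca, std$Z, std)
  }
  a1 <- run(X)
  X2 <- X
  X2[, "Pb"] <- X2[, "Pb"] + 50  # constant shift in one metal
  a2 <- run(X2)
  d1 <- a1 - matrix(a1[1, ], nrow(a1), ncol(a1), byrow = TRUE)
  d2 <- a2 - matrix(a2[1, ], nrow(a2), ncol(a2), byrow = TRUE)
  # columns may flip sign/order; compare via absolute correlation
  cors <- abs(cor(d1[-1, ], d2[-1, ]))
  expect_equal(unname(sort(apply(cors, 1, max))), c(1, 1), tolerance = 1e-6)
})

test_that("noiseless linear data is recovered exactly", {
  set.seed(26)
  apcs <- matrix(abs(rnorm(100)), 100, 1)
  y <- 2 + 3 * apcs[, 1]
  X <- cbind(y, matrix(rlnorm(100 * 7), 100))
  colnames(X) <- default_panel()
  model <- mlr_apportion(X[, 1, drop = FALSE], apcs)
  expect_equal(model$coefficients$b0, 2, tolerance = 1e-8)
  expect_equal(model$coefficients$b1, 3, tolerance = 1e-8)
  expect_equal(model$coefficients$adj_r2, 1, tolerance = 1e-8)
})

test_that("residuals are orthogonal to APCS columns and shares sum to 100", {
  mix <- generate_mixture(300, p = 3, noise_sd = 0.1, seed = 27)
  res <- apcs_mlr(mix$samples, retention = "fixed", k = 3)
  X <- conc_matrix(mix$samples)
  k <- res$pca$k
  for (i in seq_len(8)) {
    b <- as.numeric(res$model$coefficients[i, c("b0", paste0("b", 1:k))])
    fitted <- b[1] + res$apcs %*% b[-1]
    resid <- scale(X[, i] - fitted, center = FALSE,
                   scale = max(abs(X[, i])))
    for (j in seq_len(k)) {
      expect_lt(abs(sum(resid * scale(res$apcs[, j], center = FALSE,
                                      scale = max(abs(res$apcs[, j]))))), 1e-4)
    }
  }
  expect_equal(unname(rowSums(res$model$shares)), rep(100, 8),
               tolerance = 0.01)
  expect_equal(sum(res$model$overall_shares), 100, tolerance = 0.01)
})

test_that("unrotated full-rank scores span the data (adjusted R2 = 1)", {
  st <- random_table(60, seed = 28)
  std <- standardize_metals(st)
  pca <- pca_extract(std$Z, retention = "fixed", k = 8, rotate = "none")
  apcs <- apcs_scores(pca, std$Z, std)
  model <- mlr_apportion(st, apcs)
  expect_equal(model$coefficients$adj_r2, rep(1, 8), tolerance = 1e-6)
})

test_that("F-test p-values are level under the null", {
  set.seed(29)
  n <- 50
  pvals <- replicate(1000, {
    apcs <- matrix(rnorm(n * 2), n, 2)
    y <- matrix(rnorm(n), n, 1)
    colnames(y) <- "Hg"
    mlr_apportion(y, apcs)$coefficients$f_p
  })
  # rejection rate at alpha = .05 within Monte-Carlo error (3 sd ~ 0.021)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})

test_that("two-source mixtures recover per-metal shares within 5 points", {
  set.seed(30)
  n <- 1000
  s1 <- rlnorm(n, 3, 0.5)
  s2 <- rlnorm(n, 3, 0.5)
  # block profiles: metals 1-4 dominated by source 1, 5-8 by source 2
  c1 <- c(0.9, 0.8, 0.85, 0.75, 0.2, 0.15, 0.1, 0.25)
  c2 <- 1 - c1
  X <- sapply(1:8, function(i)
    c1[i] * s1 + c2[i] * s2 + abs(rnorm(n, 0, 0.02 * (c1[i] + c2[i]) *
                                          mean(s1))))
  colnames(X) <- default_panel()
  true_share1 <- 100 * c1 * mean(s1) / (c1 * mean(s1) + c2 * mean(s2))
  res <- apcs_mlr(sample_table(as.data.frame(X)), retention = "fixed", k = 2)
  sh <- res$model$shares
  # map factors to sources by correlation of APCS with true contributions
  m1 <- which.max(abs(cor(res$apcs, s1)))
  est_share1 <- sh[, m1]
  expect_lt(max(abs(est_share1 - true_share1)), 5)
})

test_that("sample order does not change the apportionment", {
  mix <- generate_mixture(120, p = 2, noise_sd = 0.05, seed = 31)
  res1 <- apcs_mlr(mix$samples, retention = "fixed", k = 2)
  df <- as.data.frame(mix$samples)
  perm <- sample(nrow(df))
  res2 <- apcs_mlr(sample_table(df[perm, ]), retention = "fixed", k = 2)
  expect_equal(res1$model$shares, res2$model$shares, tolerance = 1e-8)
  expect_equal(res1$model$overall_shares, res2$model$overall_shares,
               tolerance = 1e-8)
})
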