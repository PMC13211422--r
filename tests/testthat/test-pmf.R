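test_that("uncertainty schemes follow their published branch formulas", {
  mdl <- setNames(rep(0.06, 8), default_panel())
  X <- matrix(10, 2, 8, dimnames = list(NULL, default_panel()))
  X[1, "Hg"] <- 0.05
  epa <- build_uncertainty(X, mdl, scheme = "epa", error_fraction = 0.1)
  # below MDL: concentration substituted MDL/2, uncertainty 5/6 MDL
  expect_equal(unname(epa$X[1, "Hg"]), 0.03)
  expect_equal(unname(epa$U[1, "Hg"]), 0.05)
  expect_true(epa$below_mdl[1, "Hg"])
  # above MDL: sqrt((sigma c)^2 + (MDL/2)^2)
  expect_equal(unname(epa$U[2, "Hg"]), sqrt(1^2 + 0.03^2))
  expect_equal(round(unname(epa$U[2, "Hg"]), 5), 1.00045)

  Xp <- matrix(0.10, 1, 8, dimnames = list(NULL, default_panel()))
  pw <- build_uncertainty(Xp, mdl, scheme = "piecewise")
  expect_equal(unname(pw$U[1, "Hg"]), 0.06 / 3 + 0.2 * 0.10)  # 0.04
  Xh <- matrix(1, 1, 8, dimnames = list(NULL, default_panel()))
  pwh <- build_uncertainty(Xh, mdl, scheme = "piecewise")
  expect_equal(unname(pwh$U[1, "Hg"]), 0.06 / 3 + 0.1)
  expect_true(all(epa$U > 0) && all(pw$U > 0))

  expect_error(build_uncertainty(X, mdl[1:7], scheme = "epa"), "MDL missing")
})

test_that("an exactly factorizable matrix is fit to numerical zero", {
  mix <- generate_mixture(60, m = 8, p = 3, noise_sd = 0, seed = 40)
  X <- conc_matrix(mix$samples)
  U <- matrix(1, nrow(X), ncol(X))
  fit <- pmf_fit(X, U, 3, restarts = 5, seed = 1)
  expect_lt(fit$Q_true, 1e-4 * 60 * 8)
  expect_true(all(fit$G >= 0) && all(fit$F >= 0))
})

test_that("the objective never increases across iterations", {
  mix <- generate_mixture(80, m = 8, p = 3, noise_sd = 0.05, seed = 41)
  unc <- build_uncertainty(conc_matrix(mix$samples),
                           setNames(rep(1e-3, 8), default_panel()))
  for (s in 1:3) {
    fit <- pmf_fit(unc$X, unc$U, 3, restarts = 1, seed = s, max_iter = 300)
    dq <- diff(fit$Q_trace)
    expect_true(all(dq <= 1e-8 * pmax(fit$Q_trace[-length(fit$Q_trace)], 1)))
  }
})

test_that("rank-1 data is reproduced by a single factor", {
  set.seed(42)
  g <- rlnorm(40, 2, 0.5)
  f <- runif(8, 0.5, 2)
  X <- outer(g, f)
  colnames(X) <- default_panel()
  fit <- pmf_fit(X, matrix(1, 40, 8), 1, restarts = 3, seed = 1)
  expect_lt(max(abs(fit$G %*% fit$F - X) / mean(X)), 1e-3)
})

test_that("profile-row normalization leaves the reconstruction invariant", {
  mix <- generate_mixture(100, m = 8, p = 3, noise_sd = 0.05, seed = 43)
  X <- conc_matrix(mix$samples)
  U <- pmax(0.05 * mix$truth$X_clean, 1e-9)
  fit <- pmf_fit(X, U, 3, restarts = 2, seed = 2)
  expect_equal(unname(rowSums(fit$F)), rep(1, 3), tolerance = 1e-10)
  expect_equal(fit$Q_true, sum(((X - fit$G %*% fit$F) / U)^2),
               tolerance = 1e-10)
})

test_that("Q_robust caps extreme scaled residuals at 4", {
  E <- matrix(0, 2, 2)
  E[1, 1] <- 10
  U <- matrix(1, 2, 2)
  model <- structure(list(residuals = E, U = U), class = "pmf_fit")
  qd <- q_values(model)
  expect_equal(qd$q_true, 100)
  expect_equal(qd$q_robust, 16)
  # all residuals below the cap: ratio exactly 1
  model2 <- structure(list(residuals = E / 5, U = U), class = "pmf_fit")
  expect_equal(q_values(model2)$ratio, 1)
  expect_equal(q_values(model2)$q_true, 4)
})

test_that("scaled residual sum of squares sits near its degrees of freedom", {
  ratios <- vapply(1:20, function(s) {
    mix <- generate_mixture(100, m = 8, p = 3, noise_sd = 0.05,
                            seed = 400 + s)
    U <- pmax(0.05 * mix$truth$X_clean, 1e-9)
    fit <- pmf_fit(conc_matrix(mix$samples), U, 3, restarts = 3, seed = s,
                   max_iter = 1500)
    fit$Q_true / (100 * 8 - 3 * (100 + 8))
  }, numeric(1))
  expect_true(all(ratios > 0.7 & ratios < 1.4))
})

test_that("true profiles are recovered after optimal alignment", {
  mix <- generate_mixture(500, m = 8, p = 3, noise_sd = 0.02, seed = 44)
  U <- pmax(0.02 * mix$truth$X_clean, 1e-9)
  fit <- pmf_fit(conc_matrix(mix$samples), U, 3, restarts = 5, seed = 1)
  al <- align_profiles(fit$F, mix$truth$F)
  expect_gte(al$mean_cosine, 0.95)
  expect_setequal(al$perm, 1:3)
})

test_that("identifiability precondition is enforced", {
  X <- matrix(runif(5 * 4, 1, 2), 5, 4)
  expect_error(pmf_fit(X, matrix(1, 5, 4), 3), "identifiability")
})

test_that("factor contributions have the stated degenerate forms", {
  mix <- generate_mixture(50, m = 8, p = 3, noise_sd = 0.05, seed = 45)
  X <- conc_matrix(mix$samples)
  fit1 <- pmf_fit(X, matrix(1, 50, 8), 1, restarts = 2, seed = 1,
                  max_iter = 500)
  con1 <- pmf_contributions(fit1)
  expect_equal(unname(con1$metal_shares[, 1]), rep(100, 8), tolerance = 1e-8)
  expect_equal(unname(con1$overall_shares), 100)

  # two factors with disjoint metal support -> 100/0 share blocks
  G <- cbind(rlnorm(50, 2, 0.3), rlnorm(50, 2, 0.3))
  F <- rbind(c(rep(0.25, 4), rep(0, 4)), c(rep(0, 4), rep(0.25, 4)))
  model <- structure(list(G = G, F = F, X = G %*% F), class = "pmf_fit")
  con2 <- pmf_contributions(model)
  expect_equal(unname(con2$metal_shares[1:4, 1]), rep(100, 4))
  expect_equal(unname(con2$metal_shares[5:8, 1]), rep(0, 4))
})

test_that("factor scan finds the largest Q drop at the true source count", {
  mix <- generate_mixture(200, m = 8, p = 4, noise_sd = 0.03, seed = 11)
  U <- pmax(0.03 * mix$truth$X_clean, 1e-9)
  sc <- scan_factors(conc_matrix(mix$samples), U, p_range = 3:6,
                     bootstrap_n = 0, seed = 1, restarts = 4,
                     max_iter = 1500)
  drops <- sc$summary$rel_q_drop
  expect_equal(sc$summary$p[which.max(drops)], 4)
  expect_true(all(sc$summary$ratio <= 1 + 1e-12))
})

test_that("bootstrap mapping is complete on noise-free data and skips infeasible p", {
  mix <- generate_mixture(40, m = 8, p = 2, noise_sd = 0, seed = 46)
  X <- conc_matrix(mix$samples)
  U <- matrix(1, 40, 8)
  sc <- scan_factors(X, U, p_range = 2, bootstrap_n = 5, seed = 3,
                     restarts = 3, max_iter = 800)
  expect_equal(unname(sc$mapping[["2"]]), c(100, 100))
  expect_warning(
    scan_factors(X[1:10, ], U[1:10, ], p_range = c(2, 9), bootstrap_n = 0,
                 seed = 1, restarts = 1, max_iter = 50),
    "identifiability")
})
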