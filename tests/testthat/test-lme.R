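test_that("cluster block covariance has the nested-intercept structure", {
  vc <- variance_components(1.2, 2.5, 3.1, rho = 0.4)
  V <- cluster_block_covariance(vc, m = 3, n = 4, structure = "CS")
  expect_equal(dim(V), c(12, 12))
  expect_true(isSymmetric(V))
  expect_equal(unique(diag(V)), 1.2^2 + 2.5^2 + 3.1^2)
  # within-participant off-diagonal = sigma_gamma^2 + sigma_h^2
  expect_equal(V[1, 2], 1.2^2 + 2.5^2)
  # cross-participant entries = sigma_gamma^2 only
  expect_equal(V[1, 5], 1.2^2)

  Var <- cluster_block_covariance(vc, m = 2, n = 2, structure = "AR1")
  expect_equal(Var[1, 2], 1.2^2 + 2.5^2 + 3.1^2 * 0.4)
  # iid limit
  vc0 <- variance_components(0, 0, 2, rho = 0)
  expect_equal(cluster_block_covariance(vc0, 2, 3, "AR1"), diag(4, 6))
})

test_that("blockwise profiled log-likelihood matches the dense oracle", {
  set.seed(42)
  for (i in 1:8) {
    K <- sample(2:3, 1); m <- sample(1:3, 1)
    d <- standard_design(K, m)
    sim <- simulate_trial(d, sample(paste0("D", 1:36), 1), seed = i)
    X <- design_matrix(sample(c("M1", "M2", "M4"), 1), sim)
    g <- make_grouping(sim)
    vc <- variance_components(runif(1, 0.1, 2), runif(1, 0.5, 4),
                              runif(1, 1, 5), rho = runif(1, -0.8, 0.8))
    for (st in c("CS", "AR1")) {
      pl <- profiled_loglik(vc, X, sim$y, g, st)
      or <- dense_loglik(vc, X, sim$y, g, st)
      expect_equal(pl$loglik, or$loglik, tolerance = 1e-10)
      expect_equal(unname(pl$beta), unname(or$beta), tolerance = 1e-8)
    }
  }
})

test_that("profiled GLS reduces to OLS in the iid limit", {
  sim <- small_trial("D11")
  X <- design_matrix("M2", sim)
  vc <- variance_components(0, 0, 2, rho = 0)
  pl <- profiled_loglik(vc, X, sim$y, make_grouping(sim), "CS")
  ols <- lm.fit(X, sim$y)$coefficients
  expect_equal(unname(pl$beta), unname(ols), tolerance = 1e-10)
})

test_that("ML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  d <- standard_design(6, 6)
  sim <- simulate_trial(d, "D10", seed = 3)
  X <- design_matrix("M2", sim)
  g <- make_grouping(sim)
  dd <- as.data.frame(sim)

  f_cs <- fit_ml(X, sim$y, g, "CS")
  m_cs <- nlme::lme(y ~ treated + time, random = ~1 | cluster_id / subject_id,
                    data = dd, method = "ML")
  expect_equal(f_cs$loglik, as.numeric(stats::logLik(m_cs)), tolerance = 1e-6)
  expect_equal(unname(f_cs$beta), unname(nlme::fixef(m_cs)), tolerance = 1e-4)

  f_ar <- fit_ml(X, sim$y, g, "AR1")
  m_ar <- nlme::lme(y ~ treated + time, random = ~1 | cluster_id / subject_id,
                    data = dd, method = "ML",
                    correlation = nlme::corAR1(form = ~ time | cluster_id / subject_id))
  expect_equal(f_ar$loglik, as.numeric(stats::logLik(m_ar)), tolerance = 1e-6)
  expect_equal(unname(f_ar$beta), unname(nlme::fixef(m_ar)), tolerance = 1e-4)
  expect_equal(f_ar$varcomp$rho,
               as.numeric(coef(m_ar$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 1e-3)
})

test_that("ML recovers the generating variance components and rho", {
  d <- standard_design(12, 20)
  sim <- simulate_trial(d, "D2", seed = 77)       # flat mean, rho = +0.5
  X <- design_matrix("M1", sim)
  fit <- fit_ml(X, sim$y, make_grouping(sim), "AR1")
  expect_true(fit$converged)
  expect_equal(fit$varcomp$rho, 0.5, tolerance = 0.1)
  expect_equal(fit$varcomp$sigma, 5.44, tolerance = 0.15 * 5.44)
  expect_equal(fit$varcomp$sigma_h, 4.42, tolerance = 0.25 * 4.42)
})

test_that("fits are deterministic and respect linear equivariance", {
  sim <- small_trial("D17", K = 5, m = 4)
  X <- design_matrix("M4", sim)
  g <- make_grouping(sim)
  f1 <- fit_ml(X, sim$y, g, "CS")
  f2 <- fit_ml(X, sim$y, g, "CS")
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$loglik, f2$loglik)
  # doubling y doubles beta and quadruples the sampling variance
  f3 <- fit_ml(X, 2 * sim$y, g, "CS")
  expect_equal(unname(f3$beta), unname(2 * f1$beta), tolerance = 1e-4)
  expect_equal(unname(diag(f3$vcov_beta)), unname(4 * diag(f1$vcov_beta)),
               tolerance = 1e-3)
})

test_that("BIC identity holds and parameter counts follow the structure", {
  sim <- small_trial()
  X <- design_matrix("M1", sim)
  g <- make_grouping(sim)
  for (st in c("CS", "AR1")) {
    f <- fit_ml(X, sim$y, g, st)
    expect_equal(f$n_params, ncol(X) + if (st == "CS") 3L else 4L)
    expect_equal(f$bic, -2 * f$loglik + f$n_params * log(f$n_obs))
    expect_true(isSymmetric(f$vcov_beta, tol = 1e-10))
    expect_true(all(eigen(f$vcov_beta, only.values = TRUE)$values > -1e-10))
  }
})

test_that("CS fits are invariant to time permutation; AR1 fits are not", {
  sim <- small_trial("D10", K = 4, m = 4)
  X <- design_matrix("M1", sim)
  g <- make_grouping(sim)
  set.seed(5)
  perm <- sample(1:5)                 # relabel the 5 time steps
  g_perm <- g
  g_perm$time <- perm[g$time]
  f_cs <- fit_ml(X, sim$y, g, "CS")
  f_cs_p <- fit_ml(X, sim$y, g_perm, "CS")
  expect_equal(f_cs$loglik, f_cs_p$loglik, tolerance = 1e-7)
  expect_equal(f_cs$beta, f_cs_p$beta, tolerance = 1e-5)
  f_ar <- fit_ml(X, sim$y, g, "AR1")
  f_ar_p <- fit_ml(X, sim$y, g_perm, "AR1")
  expect_gt(abs(f_ar$loglik - f_ar_p$loglik), 1e-4)
})

test_that("CS and AR1 fixed effects on the same data agree closely", {
  d <- standard_design(8, 8)
  sim <- simulate_trial(d, "D17", seed = 13)
  f_cs <- fit_formulation(sim, "M4", "CS")
  f_ar <- fit_formulation(sim, "M4", "AR1")
  expect_equal(unname(f_cs$beta), unname(f_ar$beta), tolerance = 0.08)
})

test_that("rank-deficient design matrices raise a named error", {
  sim <- small_trial()
  X <- design_matrix("M2", sim)
  X <- cbind(X, tau_copy = X[, "tau"])
  expect_error(fit_ml(X, sim$y, make_grouping(sim), "CS"),
               "rank deficient.*tau")
})
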