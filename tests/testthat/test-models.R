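test_that("design matrices have the contracted columns and full rank", {
  d <- standard_design(12, 2)
  sim <- simulate_trial(d, "D1", seed = 4)

  X1 <- design_matrix("M1", sim)
  expect_equal(colnames(X1), c("(Intercept)", "delta"))

  X7 <- design_matrix("M7", sim)
  expect_equal(ncol(X7), 14)  # intercept + delta + kappa_2..kappa_13
  expect_equal(colnames(X7)[3:14], paste0("kappa_", 2:13))

  X8 <- design_matrix("M8", sim)
  expect_equal(ncol(X8), 24)  # + phi_3..phi_12
  expect_equal(sum(grepl("^phi_", colnames(X8))), 10)
  expect_false(any(c("phi_1", "phi_2", "phi_13") %in% colnames(X8)))

  X9 <- design_matrix("M9", sim)
  expect_equal(ncol(X9), 25)  # intercept + 12 kappa + 12 xi
  expect_equal(sum(grepl("^xi_", colnames(X9))), 12)
  expect_false("delta" %in% colnames(X9))

  for (f in paste0("M", 1:9))
    expect_equal(qr(design_matrix(f, sim))$rank, ncol(design_matrix(f, sim)))
})

test_that("unrestricted categorical interactions are aliased as claimed", {
  d <- standard_design(12, 2)
  sim <- simulate_trial(d, "D1", seed = 4)
  X8 <- design_matrix("M8", sim)
  # adding the excluded interaction columns breaks identifiability
  bad <- cbind(X8,
               phi_2 = as.numeric(sim$treated == 1 & sim$time == 2),
               phi_13 = as.numeric(sim$treated == 1 & sim$time == 13))
  expect_error(fit_ml(bad, sim$y, make_grouping(sim), "CS"),
               "rank deficient.*phi")
  # an intervention column is redundant once exposure time is categorical
  X9 <- cbind(design_matrix("M9", sim), delta = sim$treated)
  expect_error(fit_ml(X9, sim$y, make_grouping(sim), "CS"),
               "rank deficient.*delta")
})

test_that("contrast weights encode the two estimands per formulation", {
  expect_equal(contrast("M1", "six_month"), c(delta = 1))
  expect_equal(contrast("M7", "time_averaged"), c(delta = 1))
  expect_equal(contrast("M3", "six_month"), c(delta = 1, omega = 6))
  expect_equal(contrast("M3", "time_averaged"), c(delta = 1, omega = 7))
  expect_equal(contrast("M4", "six_month"), c(delta = 1, psi = 6))
  expect_equal(contrast("M5", "time_averaged"), c(psi = 6))
  expect_equal(contrast("M6", "six_month"), c(delta = 1, psi = 6))
  expect_equal(contrast("M9", "six_month"), c(xi_6 = 1))
  w8 <- contrast("M8", "time_averaged")
  expect_equal(w8[["delta"]], 1)
  expect_equal(unname(w8[paste0("phi_", 3:12)]), rep(0.1, 10))
  w9 <- contrast("M9", "time_averaged")
  expect_equal(unname(w9), rep(1 / 12, 12))
  expect_error(contrast("M9", "weekly"), "arg")
})

test_that("Wald contrast estimates follow the se = sqrt(c'Sigma c) identity", {
  sim <- small_trial("D17", K = 6, m = 4)
  fit <- fit_formulation(sim, "M4", "CS")
  w <- contrast("M4", "six_month")
  eff <- estimate_effect(fit, w)
  cvec <- setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec[names(w)] <- w
  expect_equal(eff$estimate, sum(cvec * fit$beta))
  expect_equal(eff$se, sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec)))
  expect_equal(eff$ci_low, eff$estimate - qnorm(0.975) * eff$se)
  expect_equal(eff$p, 2 * pnorm(-abs(eff$estimate / eff$se)))
  # single-parameter contrast reproduces the reported SE
  e1 <- estimate_effect(fit, c(delta = 1))
  expect_equal(e1$se, sqrt(fit$vcov_beta["delta", "delta"]))
  # degenerate contrast
  e0 <- estimate_effect(fit, c(delta = 0))
  expect_equal(c(e0$estimate, e0$se), c(0, 0))
  expect_error(estimate_effect(fit, c(xi_6 = 1)), "missing from fit")
})

test_that("adding a constant to y shifts only the intercept", {
  sim <- small_trial("D13", K = 12, m = 2)
  for (f in c("M2", "M8", "M9")) {
    fit0 <- fit_formulation(sim, f, "CS")
    shifted <- sim
    shifted$y <- sim$y + 100
    fit1 <- fit_formulation(shifted, f, "CS")
    expect_equal(fit1$beta[["(Intercept)"]],
                 fit0$beta[["(Intercept)"]] + 100, tolerance = 1e-3)
    for (e in c("six_month", "time_averaged")) {
      w <- contrast(f, e, n_steps = 13)
      expect_equal(estimate_effect(fit1, w)$estimate,
                   estimate_effect(fit0, w)$estimate, tolerance = 1e-3)
    }
  }
})

test_that("categorical exposure nests the single-step intervention model", {
  sim <- small_trial("D10", K = 6, m = 3)
  f7 <- fit_formulation(sim, "M7", "CS")
  f9 <- fit_formulation(sim, "M9", "CS")
  expect_gte(f9$loglik, f7$loglik - 1e-6)
})
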