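#' The nine candidate model formulations
#'
#' Registry of the fixed-effect formulations compared by the package. Each
#' combines the intervention indicator `x`, calendar time `t` (none,
#' continuous, or categorical) and exposure time `d` (none, continuous, or
#' categorical) in a different way:
#'
#' \describe{
#'   \item{M1}{`b0 + delta*x` — no time at all.}
#'   \item{M2}{`b0 + delta*x + tau*t` — linear calendar time.}
#'   \item{M3}{`b0 + delta*x + tau*t + omega*x*t` — intervention by
#'     continuous-time interaction.}
#'   \item{M4}{`b0 + delta*x + tau*t + psi*d` — linear calendar and
#'     exposure time.}
#'   \item{M5}{`b0 + tau*t + psi*d` — exposure effect only, no step.}
#'   \item{M6}{`b0 + delta*x + tau*t + psi*d + zeta*t^2` — adds quadratic
#'     calendar time.}
#'   \item{M7}{`b0 + delta*x + kappa_t` — categorical calendar time
#'     (the Hussey-Hughes model), reference `kappa_1 = 0`.}
#'   \item{M8}{`b0 + delta*x + kappa_t + phi_t*x` — categorical interaction;
#'     identifiability forces `phi_t = 0` for `t = 1, 2, n`, so interaction
#'     columns exist only for `t = 3 .. n-1`.}
#'   \item{M9}{`b0 + kappa_t + xi_d` — categorical calendar and exposure
#'     time, references `kappa_1 = xi_0 = 0`; an intervention column would
#'     be aliased because treatment is nested within exposure time.}
#' }
#'
#' @return A data frame with columns `id`, `time_kind`, `exposure_kind`,
#'   `label`.
#' @export
formulations <- function() {
  data.frame(
    id = paste0("M", 1:9),
    time_kind = c("none", "continuous", "continuous", "continuous",
                  "continuous", "continuous", "categorical", "categorical",
                  "categorical"),
    exposure_kind = c("none", "none", "none", "continuous", "continuous",
                      "continuous", "none", "none", "categorical"),
    label = c("delta*x",
              "delta*x + tau*t",
              "delta*x + tau*t + omega*x*t",
              "delta*x + tau*t + psi*d",
              "tau*t + psi*d",
              "delta*x + tau*t + psi*d + zeta*t^2",
              "delta*x + kappa_t",
              "delta*x + kappa_t + phi_t*x",
              "kappa_t + xi_d"),
    stringsAsFactors = FALSE)
}

check_formulation <- function(formulation) {
  if (!is.character(formulation) || length(formulation) != 1L ||
      !formulation %in% paste0("M", 1:9))
    stop("unknown formulation: expected one of M1..M9", call. = FALSE)
  formulation
}

trial_n_steps <- function(dataset) {
  d <- attr(dataset, "design")
  if (!is.null(d)) d$n_steps else max(dataset$time)
}

#' Fixed-effect design matrix for a formulation
#'
#' Builds the full-column-rank design matrix for one of the nine
#' formulations from a long-format trial dataset. Categorical calendar time
#' uses `t = 1` as the reference level (`kappa_1 = 0`) and categorical
#' exposure uses `d = 0` (`xi_0 = 0`). For M8 the interaction columns are
#' restricted to `t = 3 .. n-1`; for M9 no intervention column is included.
#' Rank is verified and an error names the aliased columns if the dataset
#' cannot identify all parameters.
#'
#' @param formulation `"M1"`..`"M9"`.
#' @param dataset A long-format trial data frame with columns `cluster_id`,
#'   `subject_id`, `time`, `treated`, `exposure`, `y` (see
#'   [simulate_trial()]).
#' @return A numeric matrix with named columns (`"(Intercept)"`, `delta`,
#'   `tau`, `omega`, `psi`, `zeta`, `kappa_<t>`, `phi_<t>`, `xi_<d>`).
#' @export
design_matrix <- function(formulation, dataset) {
  check_formulation(formulation)
  x <- dataset$treated
  t <- dataset$time
  d <- dataset$exposure
  n <- trial_n_steps(dataset)
  kappa_cols <- function() {
    cols <- sapply(2:n, function(tt) as.numeric(t == tt))
    colnames(cols) <- paste0("kappa_", 2:n)
    cols
  }
  X <- switch(formulation,
    M1 = cbind(delta = x),
    M2 = cbind(delta = x, tau = t),
    M3 = cbind(delta = x, tau = t, omega = x * t),
    M4 = cbind(delta = x, tau = t, psi = d),
    M5 = cbind(tau = t, psi = d),
    M6 = cbind(delta = x, tau = t, psi = d, zeta = t^2),
    M7 = cbind(delta = x, kappa_cols()),
    M8 = {
      phi_range <- 3:(n - 1L)
      phi <- sapply(phi_range, function(tt) as.numeric(x == 1 & t == tt))
      colnames(phi) <- paste0("phi_", phi_range)
      cbind(delta = x, kappa_cols(), phi)
    },
    M9 = {
      xi_range <- 1:(n - 1L)
      xi <- sapply(xi_range, function(dd) as.numeric(d == dd))
      colnames(xi) <- paste0("xi_", xi_range)
      cbind(kappa_cols(), xi)
    })
  X <- cbind("(Intercept)" = 1, X)
  check_full_rank(X)
  X
}

#' Contrast weights for the two intervention-effect estimands
#'
#' Returns the linear-combination weights over fitted parameter names whose
#' inner product with the fixed-effect estimates gives the requested
#' estimand: the intervention effect at six steps of exposure
#' (`"six_month"`) or the time-averaged intervention effect
#' (`"time_averaged"`). Per formulation:
#' M1/M2/M7 use `delta` for both; M3 uses `delta + 6*omega` and
#' `delta + 7*omega` (the median calendar time); M4/M6 use
#' `delta + 6*psi` for both; M5 uses `6*psi`; M8 uses `delta + phi_6` and
#' `delta + mean(phi_3..phi_{n-1})`; M9 uses `xi_6` and
#' `mean(xi_1..xi_{n-1})`.
#'
#' @inheritParams design_matrix
#' @param estimand `"six_month"` or `"time_averaged"`.
#' @param n_steps Number of calendar time steps `n` (13 for the standard
#'   12-cluster design); fixes the categorical averaging ranges.
#' @return Named numeric vector of contrast weights.
#' @export
contrast <- function(formulation, estimand = c("six_month", "time_averaged"),
                     n_steps = 13L) {
  check_formulation(formulation)
  estimand <- match.arg(estimand)
  n <- as.integer(n_steps)
  six <- estimand == "six_month"
  switch(formulation,
    M1 = c(delta = 1),
    M2 = c(delta = 1),
    M7 = c(delta = 1),
    M3 = c(delta = 1, omega = if (six) 6 else stats::median(seq_len(n))),
    M4 = c(delta = 1, psi = 6),
    M6 = c(delta = 1, psi = 6),
    M5 = c(psi = 6),
    M8 = {
      if (six) c(delta = 1, stats::setNames(1, "phi_6"))
      else {
        rng <- 3:(n - 1L)
        c(delta = 1, stats::setNames(rep(1 / length(rng), length(rng)),
                                     paste0("phi_", rng)))
      }
    },
    M9 = {
      if (six) c(xi_6 = 1)
      else {
        rng <- 1:(n - 1L)
        stats::setNames(rep(1 / length(rng), length(rng)),
                        paste0("xi_", rng))
      }
    })
}

#' Wald estimate of a linear contrast of fixed effects
#'
#' Computes `c' beta_hat` with standard error `sqrt(c' Sigma c)`, a
#' two-sided p-value and a confidence interval. The normal reference
#' distribution is the default; a t reference with `n_obs - n_fixed`
#' degrees of freedom is available.
#'
#' @param fit An `"sw_fit"` from [fit_ml()].
#' @param weights Named contrast weights (see [contrast()]); every name
#'   must be present among the fitted coefficients.
#' @param level Confidence level (default 0.95).
#' @param reference `"normal"` (Wald z) or `"t"`.
#' @param estimand Optional label stored in the result.
#' @return An object of class `"sw_effect"`: a list with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `level`, `estimand`.
#' @export
estimate_effect <- function(fit, weights, level = 0.95,
                            reference = c("normal", "t"), estimand = NA) {
  stopifnot(inherits(fit, "sw_fit"))
  reference <- match.arg(reference)
  missing_nm <- setdiff(names(weights), names(fit$beta))
  if (length(missing_nm))
    stop("contrast names missing from fit: ",
         paste(missing_nm, collapse = ", "), call. = FALSE)
  cvec <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec[names(weights)] <- weights
  est <- sum(cvec * fit$beta)
  se <- sqrt(max(drop(cvec %*% fit$vcov_beta %*% cvec), 0))
  alpha <- 1 - level
  if (reference == "normal") {
    q <- stats::qnorm(1 - alpha / 2)
    p <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_
  } else {
    df <- fit$n_obs - length(fit$beta)
    q <- stats::qt(1 - alpha / 2, df)
    p <- if (se > 0) 2 * stats::pt(-abs(est / se), df) else NA_real_
  }
  structure(list(estimate = est, se = se,
                 ci_low = est - q * se, ci_high = est + q * se,
                 p = p, level = level, estimand = estimand),
            class = "sw_effect")
}

#' @export
print.sw_effect <- function(x, ...) {
  cat(sprintf("%s effect: %.3f (SE %.3f), %g%% CI [%.3f, %.3f], p = %.3g\n",
              if (is.na(x$estimand)) "Contrast" else x$estimand,
              x$estimate, x$se, 100 * x$level, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Fit one formulation to a trial dataset
#'
#' Convenience wrapper: builds the formulation's design matrix, fits by
#' maximum likelihood under the requested within-participant covariance
#' structure, and tags the fit with the formulation id.
#'
#' @inheritParams design_matrix
#' @param structure `"CS"` or `"AR1"`.
#' @param ... Passed to [fit_ml()] (e.g. `start`).
#' @return An `"sw_fit"` with a `formulation` element.
#' @export
fit_formulation <- function(dataset, formulation, structure = c("CS", "AR1"),
                            ...) {
  structure <- match.arg(structure)
  X <- design_matrix(formulation, dataset)
  g <- data.frame(cluster = dataset$cluster_id, subject = dataset$subject_id,
                  time = dataset$time)
  fit <- fit_ml(X, dataset$y, g, structure = structure, ...)
  fit$formulation <- formulation
  fit$n_steps <- trial_n_steps(dataset)
  fit
}
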