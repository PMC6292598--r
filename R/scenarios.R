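#' Non-linear calendar-time and exposure-time trend profiles
#'
#' The scenario library uses two half/full sinusoid calendar-time trends and
#' two exposure-time trends, all in outcome (HoNOS) units:
#' \describe{
#'   \item{K1}{`2 * sin((t - 1) * pi / 12)` — half a cycle over a 13-step
#'     study, peaking (value 2) at step 7.}
#'   \item{K2}{`2 * sin((t - 1) * pi / 6)` — a full cycle, with a peak at
#'     step 4 and a trough at step 10.}
#'   \item{X1}{`sin((d - 1) * pi / 12)` for exposure `d >= 1`, 0 at `d = 0` —
#'     a gradual intervention effect that builds to 1 at six steps of
#'     exposure; note `X1(1) = 0`, so the effect starts one step after
#'     crossover.}
#'   \item{X2}{`sin((d - 1) * pi / 6)` for `d >= 1`, 0 at `d = 0` — an
#'     intervention effect that builds and then reverses.}
#' }
#'
#' @param profile `"K1"` or `"K2"` for [calendar_profile()]; `"X1"` or
#'   `"X2"` for [exposure_profile()].
#' @param t Calendar time step(s), `1..13`.
#' @param d Exposure time step(s), `0..12` (0 means still under control).
#' @return Numeric vector of trend values in outcome units.
#' @examples
#' round(calendar_profile("K1", 1:13), 2)
#' round(exposure_profile("X1", 0:12), 2)
#' @export
calendar_profile <- function(profile, t) {
  profile <- match.arg(profile, c("K1", "K2"))
  if (any(t < 1 | t > 13 | t != round(t)))
    stop("calendar time step `t` must be an integer in 1..13", call. = FALSE)
  switch(profile,
         K1 = 2 * sin((t - 1) * pi / 12),
         K2 = 2 * sin((t - 1) * pi / 6))
}

#' @rdname calendar_profile
#' @export
exposure_profile <- function(profile, d) {
  profile <- match.arg(profile, c("X1", "X2"))
  if (any(d < 0 | d > 12 | d != round(d)))
    stop("exposure time `d` must be an integer in 0..12", call. = FALSE)
  v <- switch(profile,
              X1 = sin((d - 1) * pi / 12),
              X2 = sin((d - 1) * pi / 6))
  v[d == 0] <- 0
  v
}

#' Variance components of the generating / fitted mixed model
#'
#' Bundles the standard deviations of the cluster random intercept
#' (`sigma_gamma`), the participant random intercept (`sigma_h`) and the
#' residual error (`sigma`), plus the within-participant lag-1 correlation
#' `rho` of the AR(1) residual process. Defaults are the estimates obtained
#' from the OXTEXT-7 trial data (0.96, 4.42, 5.44) that drive the simulation
#' scenarios. The composite random-intercept variance is
#' `sigma_nu^2 = sigma_gamma^2 + sigma_h^2`.
#'
#' @param sigma_gamma,sigma_h,sigma Non-negative standard deviations, in
#'   outcome units.
#' @param rho Lag-1 correlation, strictly inside (-1, 1).
#' @return An object of class `"sw_varcomp"`.
#' @export
variance_components <- function(sigma_gamma = 0.96, sigma_h = 4.42,
                                sigma = 5.44, rho = -0.5) {
  if (sigma_gamma < 0 || sigma_h < 0 || sigma < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("`rho` must lie strictly inside (-1, 1)", call. = FALSE)
  structure(list(sigma_gamma = sigma_gamma, sigma_h = sigma_h,
                 sigma = sigma, rho = rho),
            class = "sw_varcomp")
}

#' @export
print.sw_varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components: sigma_gamma = %.4g, sigma_h = %.4g, sigma = %.4g, rho = %.4g\n",
    x$sigma_gamma, x$sigma_h, x$sigma, x$rho))
  invisible(x)
}

# Raw parameter rows for the 36 scenarios.  Each consecutive pair (odd, even)
# shares a mean model; odd ids are generated with rho = -0.5, even with +0.5.
scenario_params <- function() {
  row <- function(delta = 0, tau = 0, psi = 0, kappa = "none", xi = "none")
    list(delta = delta, tau = tau, psi = psi, kappa = kappa, xi = xi)
  pairs <- list(
    row(),                                   # D1/D2:   14
    row(tau = 0.25),                         # D3/D4:   + 0.25 t
    row(kappa = "K1"),                       # D5/D6:   + kappa1
    row(kappa = "K2"),                       # D7/D8:   + kappa2
    row(delta = 2),                          # D9/D10:  + 2 x
    row(delta = 2, tau = 0.25),              # D11/D12
    row(delta = 2, tau = 0.25, psi = 0.15),  # D13/D14
    row(tau = 0.25, psi = 0.15),             # D15/D16
    row(delta = 2, tau = 0.25, psi = 0.25),  # D17/D18
    row(tau = 0.25, psi = 0.25),             # D19/D20
    row(delta = -2, tau = 0.25, psi = -0.5), # D21/D22
    row(tau = 0.25, psi = -0.5),             # D23/D24
    row(delta = 2, kappa = "K1"),            # D25/D26
    row(delta = 2, kappa = "K1", xi = "X1"), # D27/D28
    row(kappa = "K1", xi = "X1"),            # D29/D30
    row(delta = 2, kappa = "K2"),            # D31/D32
    row(delta = 2, kappa = "K2", xi = "X2"), # D33/D34
    row(kappa = "K2", xi = "X2"))            # D35/D36
  pairs
}

#' The 36 generating scenarios
#'
#' `scenario_table()` returns the full library of generating mean models
#' D1..D36. Each scenario has intercept 14 and some combination of a step
#' intervention effect (`delta` in {0, 2, -2}), a linear calendar slope
#' (`tau` in {0, 0.25} per step), a linear exposure slope (`psi` in
#' {0, 0.15, 0.25, -0.50} per step), or non-linear calendar/exposure
#' profiles (see [calendar_profile()]). Consecutive odd/even scenarios share
#' a mean model and differ only in the generating within-participant
#' correlation: `rho = -0.5` for odd ids, `+0.5` for even ids.
#'
#' @param id Scenario label, e.g. `"D17"`.
#' @param variance Optional [variance_components()] override; by default the
#'   OXTEXT-7-derived components are used with the scenario's `rho`.
#' @return `scenario_table()`: a named list of 36 `"sw_scenario"` objects.
#'   `get_scenario()`: one such object, a list with fields `id`,
#'   `intercept`, `delta`, `tau`, `psi`, `kappa_profile`, `xi_profile`,
#'   `variance`.
#' @examples
#' sc <- get_scenario("D17")
#' true_mean(sc, t = 8, d = 3, x = 1)   # 18.75
#' @export
scenario_table <- function() {
  pars <- scenario_params()
  out <- vector("list", 36L)
  names(out) <- paste0("D", 1:36)
  for (p in seq_along(pars)) {
    for (side in 1:2) {
      i <- 2L * (p - 1L) + side
      rho <- if (side == 1L) -0.5 else 0.5
      pr <- pars[[p]]
      out[[i]] <- structure(
        list(id = paste0("D", i), intercept = 14,
             delta = pr$delta, tau = pr$tau, psi = pr$psi,
             kappa_profile = pr$kappa, xi_profile = pr$xi,
             variance = variance_components(rho = rho)),
        class = "sw_scenario")
    }
  }
  out
}

#' @rdname scenario_table
#' @export
get_scenario <- function(id, variance = NULL) {
  tab <- scenario_table()
  if (!id %in% names(tab))
    stop("unknown scenario id: ", id, " (expected D1..D36)", call. = FALSE)
  sc <- tab[[id]]
  if (!is.null(variance)) {
    stopifnot(inherits(variance, "sw_varcomp"))
    sc$variance <- variance
  }
  sc
}

#' @export
print.sw_scenario <- function(x, ...) {
  terms <- "14"
  if (x$delta != 0) terms <- c(terms, sprintf("%+g x", x$delta))
  if (x$tau != 0) terms <- c(terms, sprintf("%+g t", x$tau))
  if (x$psi != 0) terms <- c(terms, sprintf("%+g d", x$psi))
  if (x$kappa_profile != "none") terms <- c(terms, paste0("+ ", x$kappa_profile, "(t)"))
  if (x$xi_profile != "none") terms <- c(terms, paste0("+ ", x$xi_profile, "(d)"))
  cat(sprintf("Scenario %s: mean = %s; rho = %g\n", x$id,
              paste(terms, collapse = " "), x$variance$rho))
  invisible(x)
}

#' Generating mean outcome for a scenario
#'
#' Evaluates the scenario's mean model at calendar time `t`, exposure time
#' `d` and treatment indicator `x`. The triple must be internally
#' consistent: `d > 0` requires `x = 1`, and `d = 0` requires `x = 0`.
#'
#' @param scenario An `"sw_scenario"` from [scenario_table()].
#' @param t Calendar time step(s).
#' @param d Exposure time step(s).
#' @param x Binary treatment indicator(s).
#' @return Mean outcome(s), in outcome units.
#' @export
true_mean <- function(scenario, t, d, x) {
  stopifnot(inherits(scenario, "sw_scenario"))
  n <- max(length(t), length(d), length(x))
  t <- rep_len(t, n); d <- rep_len(d, n); x <- rep_len(x, n)
  if (any((d > 0 & x != 1) | (d == 0 & x != 0)))
    stop("inconsistent (d, x): exposure d > 0 requires x = 1, d = 0 requires x = 0",
         call. = FALSE)
  mu <- scenario$intercept + scenario$delta * x + scenario$tau * t +
    scenario$psi * d
  if (scenario$kappa_profile != "none")
    mu <- mu + calendar_profile(scenario$kappa_profile, t)
  if (scenario$xi_profile != "none")
    mu <- mu + exposure_profile(scenario$xi_profile, d)
  mu
}
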