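#' True estimand value under a generating scenario
#'
#' Applies the estimand definitions to the generating mean model, so the
#' truth depends only on the scenario: the six-month effect is
#' `delta + 6*psi + xi(6)` and the time-averaged effect is
#' `delta + 6*psi + mean(xi(1..12))`, where `xi(.)` is the scenario's
#' non-linear exposure profile (zero if absent). Calendar-time terms do not
#' contribute: they are nuisance trends, not intervention effects.
#'
#' @param scenario An `"sw_scenario"` or scenario id.
#' @param estimand `"six_month"` or `"time_averaged"`.
#' @return True effect in outcome units.
#' @examples
#' true_effect("D9", "six_month")    # 2
#' true_effect("D27", "six_month")   # 2 + sin(5*pi/12)
#' @export
true_effect <- function(scenario, estimand = c("six_month", "time_averaged")) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "sw_scenario"))
  estimand <- match.arg(estimand)
  xi <- function(d) {
    if (scenario$xi_profile == "none") rep(0, length(d))
    else exposure_profile(scenario$xi_profile, d)
  }
  base <- scenario$delta + 6 * scenario$psi
  if (estimand == "six_month") base + xi(6) else base + mean(xi(1:12))
}

#' Mean squared error of a model fit
#'
#' Mean of the squared differences between the observed outcomes and the
#' fitted values. By default fitted values are conditional: fixed effects
#' plus the empirical best linear unbiased predictions (BLUPs) of the
#' cluster and participant random intercepts. `mode = "marginal"` uses the
#' fixed-effect predictions only.
#'
#' @param fit An `"sw_fit"` (from [fit_ml()] or [fit_formulation()]).
#' @param dataset The dataset the fit was produced from; defaults to the
#'   data stored in the fit.
#' @param mode `"conditional"` or `"marginal"`.
#' @return A single number, in squared outcome units.
#' @export
mse_of_fit <- function(fit, dataset = NULL, mode = c("conditional", "marginal")) {
  stopifnot(inherits(fit, "sw_fit"))
  mode <- match.arg(mode)
  y <- fit$y
  yhat_fixed <- drop(fit$X %*% fit$beta)
  if (mode == "marginal") return(mean((y - yhat_fixed)^2))
  vc <- fit$varcomp
  idx <- fit$idx
  s2 <- vc$sigma^2
  a2 <- vc$sigma_gamma^2 / s2
  b2 <- vc$sigma_h^2 / s2
  rho <- if (fit$structure == "AR1") vc$rho else 0
  r_sorted <- (y - yhat_fixed)[idx$ord]
  # W^{-1} r in residual-variance units; V^{-1} r = W^{-1} r / sigma^2, and
  # the sigma^2 cancels against the sigma_gamma^2 / sigma_h^2 prefactors,
  # leaving the variance ratios a2 / b2.
  wr <- drop(wsolve(a2, b2, rho, idx, matrix(r_sorted, ncol = 1),
                    fit$structure))
  blup <- numeric(idx$n)
  for (c_ in seq_len(idx$n_cluster)) {
    rows <- idx$cl_start[c_]:(idx$cl_start[c_] + idx$cl_len[c_] - 1L)
    blup[rows] <- a2 * sum(wr[rows])
  }
  for (j in seq_len(idx$n_subj)) {
    rows <- idx$subj_start[j]:(idx$subj_start[j] + idx$subj_len[j] - 1L)
    blup[rows] <- blup[rows] + b2 * sum(wr[rows])
  }
  resid_sorted <- r_sorted - blup
  mean(resid_sorted^2)
}

#' Replicate metrics for one (scenario, formulation, structure) cell
#'
#' Simulates `n_reps` trial datasets from the scenario, fits the
#' formulation under the given covariance structure, estimates both
#' intervention-effect estimands by Wald contrasts, and aggregates
#' coverage probability of the 95% CI, bias, mean CI width, mean MSE and
#' mean BIC. Replicate `r` always uses the substream seed
#' `substream_seed(master_seed, scenario, r)`, so the same replicate's
#' dataset is shared by every cell of a grid and any cell can be reproduced
#' in isolation.
#'
#' Metrics are aggregated over converged replicates; `coverage_all_reps`
#' additionally reports the coverage with all replicates in the
#' denominator.
#'
#' @param design An [standard_design()].
#' @param scenario Scenario id or object.
#' @param formulation `"M1"`..`"M9"`.
#' @param structure `"CS"` or `"AR1"`.
#' @param n_reps Number of replicates.
#' @param master_seed Integer master seed.
#' @param level Confidence level for coverage/width (default 0.95).
#' @param ci_reference `"normal"` or `"t"`.
#' @param mse_mode `"conditional"` or `"marginal"`.
#' @return A data frame of class `"sw_cell_summary"` with one row per
#'   estimand: columns `scenario`, `formulation`, `structure`, `estimand`,
#'   `truth`, `n_reps`, `n_converged`, `coverage`, `coverage_all_reps`,
#'   `bias`, `mean_estimate`, `mean_ci_width`, `mean_mse`, `mean_bic`,
#'   `valid`.
#' @export
run_cell <- function(design, scenario, formulation, structure = c("CS", "AR1"),
                     n_reps, master_seed, level = 0.95,
                     ci_reference = c("normal", "t"),
                     mse_mode = c("conditional", "marginal")) {
  structure <- match.arg(structure)
  ci_reference <- match.arg(ci_reference)
  mse_mode <- match.arg(mse_mode)
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  check_formulation(formulation)
  stopifnot(n_reps >= 1)
  estimands <- c("six_month", "time_averaged")
  truth <- vapply(estimands, function(e) true_effect(scenario, e), numeric(1))
  cw <- lapply(estimands, contrast, formulation = formulation,
               n_steps = design$n_steps)
  names(cw) <- estimands

  est <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, estimands))
  cov_ind <- width <- est
  mse <- bic <- rep(NA_real_, n_reps)
  converged <- logical(n_reps)
  warm <- NULL
  for (r in seq_len(n_reps)) {
    seed <- substream_seed(master_seed, scenario$id, r)
    dat <- simulate_trial(design, scenario, seed = seed)
    fit <- fit_formulation(dat, formulation, structure = structure,
                           start = warm)
    converged[r] <- fit$converged
    if (!fit$converged) next
    warm <- fit$varcomp
    bic[r] <- fit$bic
    mse[r] <- mse_of_fit(fit, mode = mse_mode)
    for (e in estimands) {
      eff <- estimate_effect(fit, cw[[e]], level = level,
                             reference = ci_reference, estimand = e)
      est[r, e] <- eff$estimate
      width[r, e] <- eff$ci_high - eff$ci_low
      cov_ind[r, e] <- as.numeric(eff$ci_low <= truth[e] &
                                    truth[e] <= eff$ci_high)
    }
  }
  n_conv <- sum(converged)
  valid <- n_conv > 0
  if (!valid)
    warning("no replicates converged for ", scenario$id, "/", formulation,
            "/", structure, call. = FALSE)
  agg <- function(v) if (valid) mean(v[converged]) else NA_real_
  out <- do.call(rbind, lapply(estimands, function(e) {
    data.frame(scenario = scenario$id, formulation = formulation,
               structure = structure, estimand = e, truth = truth[e],
               n_reps = n_reps, n_converged = n_conv,
               coverage = agg(cov_ind[, e]),
               coverage_all_reps = if (valid)
                 sum(cov_ind[converged, e]) / n_reps else NA_real_,
               bias = agg(est[, e]) - truth[e],
               mean_estimate = agg(est[, e]),
               mean_ci_width = agg(width[, e]),
               mean_mse = agg(mse), mean_bic = agg(bic),
               valid = valid, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("sw_cell_summary", "data.frame")
  out
}

#' Run a replicate grid over scenarios, formulations and structures
#'
#' Executes [run_cell()] for the full cross-product requested by a run
#' configuration and returns the stacked long-format summary table (two
#' rows per cell, one per estimand). All ids are validated before any
#' computation starts. Because replicate substreams depend only on
#' (scenario, replicate), every cell of the grid analyses the same
#' simulated datasets, exactly as when a set of candidate models is fitted
#' to each simulated trial.
#'
#' @param config A configuration list (or path to a YAML file readable by
#'   [read_config()]) with fields `n_clusters`, `subjects_per_cluster`,
#'   `scenarios`, `formulations`, `structures`, `n_reps`, `master_seed`,
#'   and optionally `level`, `ci_reference`, `mse_mode`, `output`.
#' @param progress Print one line per completed cell.
#' @return A long data frame of cell summaries; written as CSV to
#'   `config$output` when that field is set.
#' @export
run_grid <- function(config, progress = interactive()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config)
  design <- standard_design(cfg$n_clusters, cfg$subjects_per_cluster)
  cells <- expand.grid(scenario = cfg$scenarios,
                       formulation = cfg$formulations,
                       structure = cfg$structures,
                       stringsAsFactors = FALSE)
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res[[i]] <- run_cell(design, cells$scenario[i], cells$formulation[i],
                         cells$structure[i], n_reps = cfg$n_reps,
                         master_seed = cfg$master_seed, level = cfg$level,
                         ci_reference = cfg$ci_reference,
                         mse_mode = cfg$mse_mode)
    if (progress)
      message(sprintf("[%d/%d] %s %s %s done", i, nrow(cells),
                      cells$scenario[i], cells$formulation[i],
                      cells$structure[i]))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(cfg$output)) {
    utils::write.csv(out, cfg$output, row.names = FALSE)
  }
  out
}

#' Coverage heat map of a grid summary
#'
#' Draws a scenario-by-formulation heat map of coverage probabilities for
#' one estimand and covariance structure, in the layout used to compare
#' candidate models across scenarios. Requires ggplot2.
#'
#' @param grid_summary Output of [run_grid()].
#' @param estimand Which estimand to display.
#' @param structure Which covariance structure to display.
#' @return A ggplot object.
#' @export
coverage_heatmap <- function(grid_summary, estimand = "six_month",
                             structure = "CS") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for coverage_heatmap()", call. = FALSE)
  d <- grid_summary[grid_summary$estimand == estimand &
                      grid_summary$structure == structure, ]
  d$scenario <- factor(d$scenario,
                       levels = paste0("D", sort(as.integer(sub("^D", "", unique(d$scenario))))))
  ggplot2::ggplot(d, ggplot2::aes(x = formulation, y = scenario,
                                  fill = coverage)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", coverage)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(midpoint = 0.95, low = "firebrick",
                                  mid = "white", high = "steelblue",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "model formulation", y = "scenario",
                  fill = "coverage",
                  title = sprintf("Coverage of the %s intervention effect (%s)",
                                  estimand, structure))
}
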