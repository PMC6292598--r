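#' Derive a reproducible substream seed
#'
#' Replicate `rep` of scenario `scenario_id` under master seed `master_seed`
#' always simulates from the same substream seed, so any cell of a large
#' grid can be reproduced in isolation and grid runs are order-independent.
#' The mapping is a fixed integer hash kept below `2^31 - 1`.
#'
#' @param master_seed Integer master seed.
#' @param scenario_id Scenario label (`"D1"`..`"D36"`) or integer index.
#' @param rep Replicate number (1-based).
#' @return A single integer seed.
#' @export
substream_seed <- function(master_seed, scenario_id, rep = 1L) {
  if (is.character(scenario_id))
    scenario_id <- as.integer(sub("^D", "", scenario_id))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 48271 + as.numeric(scenario_id) * 69621) %% m
  s <- (s * 48271 + as.numeric(rep)) %% m
  as.integer(s %% m) + 1L
}

#' Simulate a closed-cohort stepped wedge trial dataset
#'
#' Generates one trial dataset under a scenario's mean model with nested
#' random intercepts and a stationary AR(1) residual process. Per cluster a
#' random intercept `gamma_k ~ N(0, sigma_gamma^2)` is drawn; per
#' participant `h_i ~ N(0, sigma_h^2)`. Each participant's residual series
#' follows the recursion `eps_t = rho * eps_{t-1} + s_t` with
#' `eps_1 ~ N(0, sigma^2)` and innovations `s_t ~ N(0, (1 - rho^2) sigma^2)`;
#' the rescaled innovation variance makes the process stationary, so
#' `Var(eps_t) = sigma^2` at every step and the lag-`r` correlation is
#' `rho^r`. The outcome is `y = mu(t, d, x) + gamma_k + h_i + eps`.
#'
#' @param design An [standard_design()].
#' @param scenario An `"sw_scenario"` (see [scenario_table()]), or a
#'   scenario id string.
#' @param seed Integer seed; all randomness flows from it, so equal seeds
#'   give bit-identical datasets.
#' @param keep_latents If `TRUE`, the latent components (`mu`, `gamma`,
#'   `h`, `epsilon`, `s`) are retained as extra columns.
#' @return A data frame of class `"sw_trial"` with one row per
#'   (participant, time step): columns `cluster_id`, `subject_id`, `time`,
#'   `treated`, `exposure`, `y`. The design is attached as attribute
#'   `"design"`.
#' @examples
#' d <- standard_design(3, 2)
#' sim <- simulate_trial(d, get_scenario("D9"), seed = 1)
#' head(sim)
#' @export
simulate_trial <- function(design, scenario, seed, keep_latents = FALSE) {
  stopifnot(inherits(design, "sw_design"))
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "sw_scenario"))
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: all randomness flows from it", call. = FALSE)
  vc <- scenario$variance
  if (abs(vc$rho) >= 1) stop("|rho| must be < 1", call. = FALSE)

  K <- design$n_clusters; n <- design$n_steps; m <- design$subjects_per_cluster
  N <- design$total_participants

  cluster_id <- rep(seq_len(K), each = m * n)
  subject_id <- rep(seq_len(N), each = n)
  time <- rep(seq_len(n), times = N)
  treated <- treatment_indicator(design, time, cluster_id)
  exposure <- exposure_time(design, time, cluster_id)
  mu <- true_mean(scenario, time, exposure, treated)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  gamma_k <- stats::rnorm(K, 0, vc$sigma_gamma)
  h_i <- stats::rnorm(N, 0, vc$sigma_h)
  # stationary AR(1) residuals, one series of length n per participant
  rho <- vc$rho
  eps <- matrix(0, nrow = n, ncol = N)
  innov <- matrix(stats::rnorm(n * N, 0, vc$sigma * sqrt(1 - rho^2)),
                  nrow = n, ncol = N)
  eps[1L, ] <- stats::rnorm(N, 0, vc$sigma)
  innov[1L, ] <- eps[1L, ]
  if (n > 1L)
    for (t in 2:n) eps[t, ] <- rho * eps[t - 1L, ] + innov[t, ]

  eps_vec <- as.vector(eps)           # time fastest, matching row order
  y <- mu + gamma_k[cluster_id] + h_i[subject_id] + eps_vec

  out <- data.frame(cluster_id = cluster_id, subject_id = subject_id,
                    time = time, treated = treated, exposure = exposure,
                    y = y)
  if (isTRUE(keep_latents)) {
    out$mu <- mu
    out$gamma <- gamma_k[cluster_id]
    out$h <- h_i[subject_id]
    out$epsilon <- eps_vec
    out$s <- as.vector(innov)
  }
  attr(out, "design") <- design
  attr(out, "scenario_id") <- scenario$id
  class(out) <- c("sw_trial", "data.frame")
  out
}
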