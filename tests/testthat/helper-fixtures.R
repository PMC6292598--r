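# Shared fixtures and independent oracles for the test suite.

# Dense full-covariance Gaussian log-density oracle, built directly from the
# grouping columns (no blocking, no Woodbury): an independent check of the
# blockwise likelihood path.
dense_loglik <- function(varcomp, X, y, grouping, structure) {
  ord <- order(grouping$cluster, grouping$subject, grouping$time)
  X <- as.matrix(X)[ord, , drop = FALSE]
  y <- y[ord]
  g <- grouping[ord, ]
  N <- length(y)
  same_cluster <- outer(g$cluster, g$cluster, "==")
  subj_key <- paste(g$cluster, g$subject)
  same_subject <- outer(subj_key, subj_key, "==")
  dt <- abs(outer(g$time, g$time, "-"))
  Rw <- if (structure == "AR1") varcomp$rho^dt else (dt == 0) * 1
  V <- varcomp$sigma_gamma^2 * same_cluster +
    varcomp$sigma_h^2 * same_subject +
    varcomp$sigma^2 * Rw * same_subject
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ll <- -0.5 * (N * log(2 * pi) +
                  as.numeric(determinant(V, logarithm = TRUE)$modulus) +
                  as.numeric(t(r) %*% Vi %*% r))
  list(loglik = ll, beta = drop(beta))
}

make_grouping <- function(dataset) {
  data.frame(cluster = dataset$cluster_id, subject = dataset$subject_id,
             time = dataset$time)
}

# small simulated dataset used by several files
small_trial <- function(scenario = "D9", K = 4, m = 3, seed = 7) {
  simulate_trial(standard_design(K, m), get_scenario(scenario), seed = seed)
}
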