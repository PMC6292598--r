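#' Marginal covariance of one cluster's stacked observations
#'
#' Builds the dense covariance matrix implied by the nested random-intercept
#' model for a single cluster of `m` participants observed at `n` equally
#' spaced time steps, stacked participant-by-participant (time fastest).
#' The matrix is
#' `sigma_gamma^2 * J + I_m (x) (sigma_h^2 * J_n + R)`, where `J` is the
#' all-ones matrix and the within-participant residual block `R` is
#' `sigma^2 * I` under compound symmetry (`"CS"`) or
#' `R[a, b] = sigma^2 * rho^|a-b|` under `"AR1"`.
#'
#' This dense form is intended for small problems and for validating the
#' blockwise likelihood; the fitting path never materialises it.
#'
#' @param varcomp A [variance_components()] object.
#' @param m Participants per cluster.
#' @param n Time steps per participant.
#' @param structure `"CS"` or `"AR1"`.
#' @return A dense `(m * n) x (m * n)` covariance matrix.
#' @export
cluster_block_covariance <- function(varcomp, m, n, structure = c("CS", "AR1")) {
  structure <- match.arg(structure)
  stopifnot(inherits(varcomp, "sw_varcomp"), m >= 1, n >= 1)
  R <- if (structure == "CS") {
    diag(varcomp$sigma^2, n)
  } else {
    varcomp$sigma^2 * varcomp$rho^abs(outer(seq_len(n), seq_len(n), "-"))
  }
  A <- varcomp$sigma_h^2 * matrix(1, n, n) + R
  V <- varcomp$sigma_gamma^2 * matrix(1, m * n, m * n)
  for (j in seq_len(m)) {
    idx <- ((j - 1L) * n + 1L):(j * n)
    V[idx, idx] <- V[idx, idx] + A
  }
  V
}

# ---- internal indexing of (cluster, subject, time) groupings ----------------

# Precomputes the sorted block layout used by the blockwise likelihood.
# Rows are sorted by (cluster, subject, time); subjects are contiguous runs
# within contiguous cluster runs.  Each subject is assigned a "pattern" (its
# observation-time vector); balanced designs have a single shared pattern,
# enabling a vectorised fast path.
sw_index <- function(cluster, subject, time) {
  stopifnot(length(cluster) == length(subject),
            length(subject) == length(time))
  ord <- order(cluster, subject, time)
  cl <- cluster[ord]; su <- subject[ord]; ti <- as.numeric(time[ord])
  key <- paste(cl, su, sep = "\r")
  subj_run <- rle(key)
  n_subj <- length(subj_run$lengths)
  subj_len <- subj_run$lengths
  subj_end <- cumsum(subj_len)
  subj_start <- subj_end - subj_len + 1L
  subj_cluster <- cl[subj_start]
  if (any(vapply(seq_len(n_subj), function(j)
        anyDuplicated(ti[subj_start[j]:subj_end[j]]) > 0L, logical(1))))
    stop("duplicate (subject, time) rows", call. = FALSE)
  pat_key <- vapply(seq_len(n_subj), function(j)
    paste(ti[subj_start[j]:subj_end[j]], collapse = ","), character(1))
  pat_levels <- unique(pat_key)
  pat_id <- match(pat_key, pat_levels)
  patterns <- lapply(pat_levels, function(k) as.numeric(strsplit(k, ",")[[1]]))
  cl_run <- rle(as.character(cl))
  cl_len <- cl_run$lengths
  cl_end <- cumsum(cl_len)
  cl_start <- cl_end - cl_len + 1L
  subj_of_cluster <- split(seq_len(n_subj),
                           findInterval(subj_start, cl_start))
  list(ord = ord, n = length(ord), n_subj = n_subj,
       subj_start = subj_start, subj_len = subj_len,
       subj_cluster = subj_cluster, pat_id = pat_id, patterns = patterns,
       cl_start = cl_start, cl_len = cl_len, n_cluster = length(cl_len),
       subj_of_cluster = subj_of_cluster,
       balanced = length(patterns) == 1L)
}

# Per-pattern within-subject matrix A = C(rho) + b2 * J in residual-variance
# units, with C = I (CS) or C[a,b] = rho^|t_a - t_b| (AR1).
pattern_terms <- function(times, b2, rho, structure) {
  n <- length(times)
  C <- if (structure == "CS") diag(1, n) else rho^abs(outer(times, times, "-"))
  A <- C + b2
  cA <- tryCatch(chol(A), error = function(e)
    stop("within-subject covariance block is not positive definite",
         call. = FALSE))
  Ainv <- chol2inv(cA)
  g <- rowSums(Ainv)
  list(Ainv = Ainv, logdet = 2 * sum(log(diag(cA))), g = g, u = sum(g))
}

# Z' W^{-1} Z and log|W| where W is the marginal covariance in units of the
# residual variance: W = a2 * 1 1' (per cluster) + blockdiag_subject(A).
# Uses the exact two-level Woodbury identity: subject blocks are inverted
# directly (n <= number of time steps), the cluster random intercept enters
# as a rank-one correction per cluster.  Z must already be in idx$ord order.
gls_components <- function(a2, b2, rho, idx, Z, structure) {
  q <- ncol(Z)
  pats <- lapply(idx$patterns, pattern_terms, b2 = b2, rho = rho,
                 structure = structure)
  ZtWZ <- matrix(0, q, q)
  logdet <- 0
  if (idx$balanced) {
    pt <- pats[[1L]]
    np <- length(idx$patterns[[1L]])
    M <- matrix(pt$Ainv %*% matrix(Z, nrow = np), nrow = nrow(Z))
    for (c_ in seq_len(idx$n_cluster)) {
      rows <- idx$cl_start[c_]:(idx$cl_start[c_] + idx$cl_len[c_] - 1L)
      m_c <- idx$cl_len[c_] / np
      Mc <- M[rows, , drop = FALSE]
      S1 <- crossprod(Z[rows, , drop = FALSE], Mc)
      gZ <- colSums(Mc)
      w <- m_c * pt$u
      f <- a2 / (1 + a2 * w)
      ZtWZ <- ZtWZ + S1 - f * tcrossprod(gZ)
      logdet <- logdet + m_c * pt$logdet + log1p(a2 * w)
    }
  } else {
    for (c_ in seq_len(idx$n_cluster)) {
      S1 <- matrix(0, q, q)
      gZ <- numeric(q)
      w <- 0
      for (j in idx$subj_of_cluster[[c_]]) {
        rows <- idx$subj_start[j]:(idx$subj_start[j] + idx$subj_len[j] - 1L)
        pt <- pats[[idx$pat_id[j]]]
        Mj <- pt$Ainv %*% Z[rows, , drop = FALSE]
        S1 <- S1 + crossprod(Z[rows, , drop = FALSE], Mj)
        gZ <- gZ + colSums(Mj)
        w <- w + pt$u
        logdet <- logdet + pt$logdet
      }
      f <- a2 / (1 + a2 * w)
      ZtWZ <- ZtWZ + S1 - f * tcrossprod(gZ)
      logdet <- logdet + log1p(a2 * w)
    }
  }
  list(ZtWZ = ZtWZ, logdet = logdet)
}

# W^{-1} Z (same scaled covariance as gls_components); Z in idx$ord order.
wsolve <- function(a2, b2, rho, idx, Z, structure) {
  Z <- as.matrix(Z)
  pats <- lapply(idx$patterns, pattern_terms, b2 = b2, rho = rho,
                 structure = structure)
  out <- matrix(0, nrow(Z), ncol(Z))
  for (c_ in seq_len(idx$n_cluster)) {
    subj <- idx$subj_of_cluster[[c_]]
    w <- 0
    gvec_rows <- integer(0)
    for (j in subj) {
      rows <- idx$subj_start[j]:(idx$subj_start[j] + idx$subj_len[j] - 1L)
      pt <- pats[[idx$pat_id[j]]]
      out[rows, ] <- pt$Ainv %*% Z[rows, , drop = FALSE]
      w <- w + pt$u
    }
    rows_c <- idx$cl_start[c_]:(idx$cl_start[c_] + idx$cl_len[c_] - 1L)
    g_c <- numeric(length(rows_c))
    off <- idx$cl_start[c_] - 1L
    for (j in subj) {
      rows <- idx$subj_start[j]:(idx$subj_start[j] + idx$subj_len[j] - 1L)
      g_c[rows - off] <- pats[[idx$pat_id[j]]]$g
    }
    f <- a2 / (1 + a2 * w)
    corr <- colSums(out[rows_c, , drop = FALSE])
    out[rows_c, ] <- out[rows_c, , drop = FALSE] - f * outer(g_c, corr)
  }
  out
}

check_grouping <- function(grouping, n) {
  if (!is.data.frame(grouping) ||
      !all(c("cluster", "subject", "time") %in% names(grouping)))
    stop("`grouping` must be a data frame with columns cluster, subject, time",
         call. = FALSE)
  if (nrow(grouping) != n)
    stop("`grouping` must have one row per observation", call. = FALSE)
  grouping
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Profiled Gaussian log-likelihood at fixed variance components
#'
#' Evaluates the exact marginal Gaussian log-likelihood of the
#' nested-intercept mixed model at the supplied variance components, with
#' the fixed effects profiled out by generalised least squares:
#' `beta_hat = (X' V^-1 X)^-1 X' V^-1 y`, computed blockwise per cluster.
#' The within-participant residual covariance is compound-symmetric
#' (`"CS"`: `sigma^2 I`) or first-order autoregressive (`"AR1"`:
#' `sigma^2 rho^|t_a - t_b|`).
#'
#' @param varcomp A [variance_components()] object (under `"CS"` its `rho`
#'   is ignored).
#' @param X Fixed-effect design matrix (full column rank).
#' @param y Outcome vector.
#' @param grouping Data frame with columns `cluster`, `subject`, `time`,
#'   one row per observation.
#' @param structure `"CS"` or `"AR1"`.
#' @return A list with `loglik`, `beta` (named GLS estimates) and
#'   `vcov_beta` (`(X' V^-1 X)^-1`).
#' @export
profiled_loglik <- function(varcomp, X, y, grouping, structure = c("CS", "AR1")) {
  structure <- match.arg(structure)
  stopifnot(inherits(varcomp, "sw_varcomp"))
  X <- as.matrix(X)
  grouping <- check_grouping(grouping, length(y))
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (varcomp$sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  check_full_rank(X)
  idx <- sw_index(grouping$cluster, grouping$subject, grouping$time)
  s2 <- varcomp$sigma^2
  a2 <- varcomp$sigma_gamma^2 / s2
  b2 <- varcomp$sigma_h^2 / s2
  rho <- if (structure == "AR1") varcomp$rho else 0
  Z <- cbind(X, y)[idx$ord, , drop = FALSE]
  comp <- gls_components(a2, b2, rho, idx, Z, structure)
  p <- ncol(X)
  XtWX <- comp$ZtWZ[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- comp$ZtWZ[seq_len(p), p + 1L]
  ytWy <- comp$ZtWZ[p + 1L, p + 1L]
  beta <- solve(XtWX, XtWy)
  rss <- max(ytWy - sum(beta * XtWy), 0)
  n_obs <- idx$n
  ll <- -0.5 * (n_obs * log(2 * pi) + n_obs * log(s2) + comp$logdet + rss / s2)
  vcov <- s2 * solve(XtWX)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(loglik = as.numeric(ll), beta = beta, vcov_beta = vcov)
}

# Profiled objective used inside fit_ml: the residual variance is profiled
# out in closed form, leaving only the variance ratios (and rho under AR1).
# Returns -2 * profile log-likelihood, or a large penalty off the domain.
profile_objective <- function(par, idx, Z, n_fixed, structure) {
  if (any(!is.finite(par)) || any(abs(par) > 20)) return(1e10)
  a2 <- exp(2 * par[1L]); b2 <- exp(2 * par[2L])
  rho <- if (structure == "AR1") tanh(par[3L]) else 0
  comp <- tryCatch(gls_components(a2, b2, rho, idx, Z, structure),
                   error = function(e) NULL)
  if (is.null(comp)) return(1e10)
  XtWX <- comp$ZtWZ[seq_len(n_fixed), seq_len(n_fixed), drop = FALSE]
  XtWy <- comp$ZtWZ[seq_len(n_fixed), n_fixed + 1L]
  ytWy <- comp$ZtWZ[n_fixed + 1L, n_fixed + 1L]
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  rss <- ytWy - sum(beta * XtWy)
  if (!is.finite(rss) || rss <= 0) return(1e10)
  n_obs <- idx$n
  n_obs * log(rss / n_obs) + comp$logdet + n_obs * (log(2 * pi) + 1)
}

#' Maximum-likelihood fit of the nested-intercept mixed model
#'
#' Maximises the marginal Gaussian likelihood over the variance components
#' (cluster-intercept SD, participant-intercept SD, residual SD, and the
#' AR(1) correlation when `structure = "AR1"`), with the fixed effects
#' profiled out by GLS and the residual variance profiled out in closed
#' form. Optimisation is unconstrained on transformed parameters (log SD
#' ratios, `atanh(rho)`), so boundary solutions such as a near-zero cluster
#' variance are reported rather than rejected. Nelder-Mead with a relative
#' tolerance of 1e-8 is used; on non-convergence a second
#' moment-based start is tried and the better solution kept.
#'
#' @inheritParams profiled_loglik
#' @param start Optional [variance_components()] giving starting values.
#' @param control Optional list overriding `optim` control parameters.
#' @return An object of class `"sw_fit"`: a list with `beta`, `vcov_beta`,
#'   `varcomp` (estimated components; `rho` only meaningful under AR1),
#'   `loglik`, `bic`, `n_obs`, `n_params` (fixed effects + 3 variance
#'   parameters under CS, + 4 under AR1), `converged`, `structure`.
#' @examples
#' d <- standard_design(4, 3)
#' sim <- simulate_trial(d, get_scenario("D9"), seed = 2)
#' X <- cbind("(Intercept)" = 1, delta = sim$treated)
#' g <- data.frame(cluster = sim$cluster_id, subject = sim$subject_id,
#'                 time = sim$time)
#' fit <- fit_ml(X, sim$y, g, structure = "CS")
#' fit$beta
#' @export
fit_ml <- function(X, y, grouping, structure = c("CS", "AR1"), start = NULL,
                   control = list()) {
  structure <- match.arg(structure)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  grouping <- check_grouping(grouping, length(y))
  check_full_rank(X)
  idx <- sw_index(grouping$cluster, grouping$subject, grouping$time)
  Z <- cbind(X, y)[idx$ord, , drop = FALSE]
  p <- ncol(X)
  npar <- if (structure == "AR1") 3L else 2L

  starts <- list()
  if (!is.null(start)) {
    stopifnot(inherits(start, "sw_varcomp"))
    s <- max(start$sigma, 1e-6)
    s0 <- c(log(max(start$sigma_gamma / s, 1e-4)),
            log(max(start$sigma_h / s, 1e-4)))
    if (npar == 3L) s0 <- c(s0, atanh(min(max(start$rho, -0.99), 0.99)))
    starts <- list(s0)
  }
  starts <- c(starts, list(c(log(0.2), log(0.8), 0)[seq_len(npar)]),
              list(c(log(0.05), log(0.3), 0)[seq_len(npar)]))

  ctrl <- utils::modifyList(list(reltol = 1e-10, maxit = 2000), control)
  best <- NULL
  for (s0 in starts) {
    opt <- stats::optim(s0, profile_objective, idx = idx, Z = Z, n_fixed = p,
                        structure = structure, method = "Nelder-Mead",
                        control = ctrl)
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (best$convergence == 0 && best$value < 1e9) break
  }
  converged <- best$convergence == 0 && best$value < 1e9

  par <- best$par
  a2 <- exp(2 * par[1L]); b2 <- exp(2 * par[2L])
  rho <- if (structure == "AR1") tanh(par[3L]) else 0
  comp <- gls_components(a2, b2, rho, idx, Z, structure)
  XtWX <- comp$ZtWZ[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- comp$ZtWZ[seq_len(p), p + 1L]
  ytWy <- comp$ZtWZ[p + 1L, p + 1L]
  beta <- solve(XtWX, XtWy)
  rss <- max(ytWy - sum(beta * XtWy), .Machine$double.eps)
  n_obs <- idx$n
  s2 <- rss / n_obs
  vc <- variance_components(sigma_gamma = sqrt(a2 * s2),
                            sigma_h = sqrt(b2 * s2),
                            sigma = sqrt(s2),
                            rho = rho)
  ll <- -0.5 * (n_obs * log(2 * pi) + n_obs * log(s2) + comp$logdet + rss / s2)
  vcov <- s2 * solve(XtWX)
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  n_params <- p + npar + 1L   # fixed effects + SD ratios + residual variance
  fit <- structure(
    list(beta = beta, vcov_beta = vcov, varcomp = vc,
         loglik = as.numeric(ll),
         bic = -2 * as.numeric(ll) + n_params * log(n_obs),
         n_obs = n_obs, n_params = n_params, converged = converged,
         structure = structure, optim = best[c("value", "counts", "convergence")],
         X = X, y = y, grouping = grouping, idx = idx),
    class = "sw_fit")
  fit
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(sprintf("ML mixed-model fit (%s residual structure)%s\n", x$structure,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  est <- cbind(Estimate = x$beta, `Std.Error` = sqrt(diag(x$vcov_beta)))
  print(round(est, 4))
  cat(sprintf("sigma_gamma = %.3f, sigma_h = %.3f, sigma = %.3f",
              x$varcomp$sigma_gamma, x$varcomp$sigma_h, x$varcomp$sigma))
  if (x$structure == "AR1") cat(sprintf(", rho = %.3f", x$varcomp$rho))
  cat(sprintf("\nlogLik = %.2f, BIC = %.2f (n = %d, params = %d)\n",
              x$loglik, x$bic, x$n_obs, x$n_params))
  invisible(x)
}

#' @export
logLik.sw_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
BIC.sw_fit <- function(object, ...) object$bic

#' Serialize a fit to a single flat row
#'
#' @param fit An `"sw_fit"`.
#' @return A one-row data frame with estimates, standard errors, variance
#'   components, log-likelihood, BIC and convergence flag.
#' @export
fit_as_row <- function(fit) {
  stopifnot(inherits(fit, "sw_fit"))
  se <- sqrt(diag(fit$vcov_beta))
  out <- c(as.list(fit$beta),
           stats::setNames(as.list(se), paste0("se_", names(fit$beta))),
           list(sigma_gamma = fit$varcomp$sigma_gamma,
                sigma_h = fit$varcomp$sigma_h, sigma = fit$varcomp$sigma,
                rho = if (fit$structure == "AR1") fit$varcomp$rho else NA_real_,
                loglik = fit$loglik, bic = fit$bic,
                converged = fit$converged))
  as.data.frame(out, check.names = FALSE)
}
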