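#' Standard stepped wedge design
#'
#' Construct the standard closed-cohort stepped wedge layout: all clusters
#' start under the control condition at time step 1, and exactly one cluster
#' crosses over to the intervention at the start of each subsequent step, so
#' there is one more time step than there are clusters. Once a cluster has
#' crossed over it never reverts to control.
#'
#' @param n_clusters Number of clusters `K` (at least 2).
#' @param subjects_per_cluster Number of participants `m` followed in each
#'   cluster at every time step (closed cohort).
#' @param seed Optional integer. When supplied, the rollout order (which
#'   cluster crosses over at which step) is a seeded random permutation of
#'   steps `2..n`; when absent, cluster `k` crosses over at step `k + 1`.
#'
#' @return An object of class `"sw_design"`: a list with elements
#'   `n_clusters`, `n_steps` (`= n_clusters + 1`), `subjects_per_cluster`,
#'   `crossover_step` (integer vector of length `K`, values in `2..n`),
#'   and `total_participants` (`= K * m`).
#'
#' @examples
#' d <- standard_design(12, 20)
#' d$n_steps               # 13
#' d$total_participants    # 240
#' treatment_indicator(d, t = 2, k = 1)
#' @export
standard_design <- function(n_clusters, subjects_per_cluster, seed = NULL) {
  if (length(n_clusters) != 1L || !is.finite(n_clusters) || n_clusters < 2 ||
      n_clusters != round(n_clusters))
    stop("`n_clusters` must be a single integer >= 2", call. = FALSE)
  if (length(subjects_per_cluster) != 1L || !is.finite(subjects_per_cluster) ||
      subjects_per_cluster < 1 || subjects_per_cluster != round(subjects_per_cluster))
    stop("`subjects_per_cluster` must be a single integer >= 1", call. = FALSE)
  K <- as.integer(n_clusters)
  m <- as.integer(subjects_per_cluster)
  n <- K + 1L
  steps <- 2:n
  if (!is.null(seed)) {
    cross <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(as.integer(seed))
      sample(steps)
    })
  } else {
    cross <- steps
  }
  new_sw_design(K, n, m, as.integer(cross))
}

new_sw_design <- function(K, n, m, crossover_step) {
  stopifnot(length(crossover_step) == K, all(crossover_step >= 2L),
            all(crossover_step <= n))
  structure(
    list(n_clusters = K, n_steps = n, subjects_per_cluster = m,
         crossover_step = crossover_step, total_participants = K * m),
    class = "sw_design")
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Stepped wedge design:", x$n_clusters, "clusters x", x$n_steps,
      "time steps,", x$subjects_per_cluster, "participants per cluster",
      paste0("(N = ", x$total_participants, ")\n"))
  cat("Crossover steps:", paste(x$crossover_step, collapse = " "), "\n")
  invisible(x)
}

check_design_index <- function(design, t, k) {
  if (any(t < 1 | t > design$n_steps | t != round(t)))
    stop("time step `t` out of range 1..", design$n_steps, call. = FALSE)
  if (any(k < 1 | k > design$n_clusters | k != round(k)))
    stop("cluster index `k` out of range 1..", design$n_clusters, call. = FALSE)
}

#' Treatment and exposure-time indicators
#'
#' `treatment_indicator()` returns the binary indicator `x[t,k]`: 1 if
#' cluster `k` is under the intervention at calendar time step `t`.
#' `exposure_time()` returns `d[t,k]`, the number of time steps (inclusive)
#' that the intervention has been in place in cluster `k` at step `t`; it is
#' 0 while the cluster is under control and 1 at the first treated step, so
#' its maximum over the standard design is `n - 1`.
#'
#' Both are vectorised over `t` and `k` (recycled to a common length).
#'
#' @param design An [standard_design()] object.
#' @param t Calendar time step(s) in `1..n`.
#' @param k Cluster index(es) in `1..K`.
#' @return Integer vector.
#' @examples
#' d <- standard_design(3, 1)
#' treatment_matrix(d)      # the upper-triangular wedge
#' exposure_time(d, t = 4, k = 1)
#' @export
treatment_indicator <- function(design, t, k) {
  check_design_index(design, t, k)
  as.integer(t >= design$crossover_step[k])
}

#' @rdname treatment_indicator
#' @export
exposure_time <- function(design, t, k) {
  check_design_index(design, t, k)
  d <- t - design$crossover_step[k] + 1L
  as.integer(pmax(d, 0L))
}

#' @rdname treatment_indicator
#' @export
treatment_matrix <- function(design) {
  n <- design$n_steps; K <- design$n_clusters
  m <- outer(seq_len(n), design$crossover_step, ">=") * 1L
  dimnames(m) <- list(t = seq_len(n), cluster = seq_len(K))
  m
}

#' Read or write a rollout schedule as CSV
#'
#' The schedule file has columns `cluster_id` and `crossover_step`, one row
#' per cluster, recording which time step each cluster first receives the
#' intervention. This is the minimal information needed to reproduce a given
#' rollout.
#'
#' @param design An `sw_design`.
#' @param path File path.
#' @param subjects_per_cluster Cohort size per cluster to attach when reading
#'   (the schedule itself does not store it).
#' @return `read_design_csv()` returns an `sw_design`; `write_design_csv()`
#'   returns `path` invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(
    data.frame(cluster_id = seq_len(design$n_clusters),
               crossover_step = design$crossover_step),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path, subjects_per_cluster = 1L) {
  df <- utils::read.csv(path)
  need <- c("cluster_id", "crossover_step")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$cluster_id), ]
  K <- nrow(df)
  new_sw_design(K, K + 1L, as.integer(subjects_per_cluster),
                as.integer(df$crossover_step))
}
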