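utils::globalVariables(c("formulation", "scenario", "coverage"))

trial_schema <- c("cluster_id", "subject_id", "time", "treated", "exposure", "y")

validate_trial <- function(df, path = "<data>") {
  missing_cols <- setdiff(trial_schema, names(df))
  if (length(missing_cols))
    stop(path, ": missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) stop(path, ": no data rows", call. = FALSE)
  dup <- duplicated(df[c("subject_id", "time")])
  if (any(dup))
    stop(path, ": duplicate (subject_id, time) at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  bad <- which((df$exposure > 0 & df$treated != 1) |
                 (df$exposure == 0 & df$treated != 0))
  if (length(bad))
    stop(path, ": inconsistent treated/exposure (exposure must be 0 under ",
         "control and positive under intervention) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  # exposure must advance by exactly one treated step
  chk <- df[order(df$subject_id, df$time), ]
  by_subj <- split(seq_len(nrow(chk)), chk$subject_id)
  for (rows in by_subj) {
    e <- chk$exposure[rows]
    de <- diff(e)
    if (any(de < 0) || any(de > 1))
      stop(path, ": exposure must be non-decreasing in steps of at most 1 ",
           "within a subject (subject ", chk$subject_id[rows[1]], ")",
           call. = FALSE)
  }
  class(df) <- c("sw_trial", class(df)[class(df) != "sw_trial"])
  df
}

#' Read and write long-format trial datasets as CSV
#'
#' The on-disk schema is one row per (participant, time step) with header
#' `cluster_id, subject_id, time, treated, exposure, y` — the same schema
#' produced by [simulate_trial()] and expected by the re-analysis mode.
#' Reading validates internal consistency: unique (subject, time) pairs,
#' `exposure = 0` exactly when `treated = 0`, and exposure advancing by one
#' per treated step.
#'
#' @param dataset A trial data frame.
#' @param path File path.
#' @return `read_trial_csv()` returns a validated `"sw_trial"` data frame;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[trial_schema], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop(path, ": not a readable CSV (",
                                          conditionMessage(e), ")",
                                          call. = FALSE))
  validate_trial(df, path)
}

#' Map a raw long-format table onto the trial schema
#'
#' Heuristically maps column names as found in deposited trial workbooks
#' (e.g. a cluster / community mental-health-team identifier, a study-month
#' column and a total-outcome-score column) onto the package's trial
#' schema, deriving the exposure time from each cluster's first treated
#' month when no exposure column is present. Unmappable inputs raise an
#' error reporting the observed header.
#'
#' @param df A data frame as read from the workbook or CSV.
#' @return A validated `"sw_trial"` data frame.
#' @export
map_trial_frame <- function(df) {
  nm <- tolower(names(df))
  pick <- function(patterns) {
    for (p in patterns) {
      hit <- grep(p, nm)
      if (length(hit)) return(hit[1L])
    }
    NA_integer_
  }
  ci <- pick(c("^cluster", "cmht", "team", "centre", "center", "site"))
  si <- pick(c("^subject", "^participant", "^patient", "\\bid$", "^id$"))
  ti <- pick(c("^time$", "month", "^step", "^t$"))
  xi <- pick(c("^treat", "^interv", "^x$", "arm", "condition"))
  yi <- pick(c("^y$", "honos", "outcome", "score", "total"))
  di <- pick(c("^exposure", "^d$"))
  need <- c(cluster = ci, subject = si, time = ti, outcome = yi)
  if (any(is.na(need)))
    stop("could not map column(s) ",
         paste(names(need)[is.na(need)], collapse = ", "),
         " from observed header: ", paste(names(df), collapse = ", "),
         call. = FALSE)
  out <- data.frame(cluster_id = df[[ci]], subject_id = df[[si]],
                    time = as.numeric(df[[ti]]), y = as.numeric(df[[yi]]))
  if (!is.na(xi)) {
    out$treated <- as.integer(as.numeric(df[[xi]]) > 0)
  } else if (!is.na(di)) {
    out$treated <- as.integer(as.numeric(df[[di]]) > 0)
  } else {
    stop("could not map a treatment or exposure column from observed ",
         "header: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (!is.na(di)) {
    out$exposure <- as.numeric(df[[di]])
  } else {
    # first treated month per cluster defines the crossover step
    first_treated <- tapply(ifelse(out$treated == 1, out$time, NA),
                            out$cluster_id, min, na.rm = TRUE)
    s_k <- as.numeric(first_treated[as.character(out$cluster_id)])
    out$exposure <- as.numeric(pmax(out$time - s_k + 1, 0) * out$treated)
  }
  out <- out[c("cluster_id", "subject_id", "time", "treated", "exposure", "y")]
  out <- out[stats::complete.cases(out), ]
  validate_trial(out)
}

#' Read a deposited trial workbook (XLSX)
#'
#' Reads the first sheet of an XLSX workbook holding a long-format record
#' of participant-level outcome totals by cluster and study month (the
#' shape of the OXTEXT-7 minimal dataset) and maps it onto the trial schema
#' via [map_trial_frame()]. Requires the readxl package.
#'
#' @param path Path to the workbook.
#' @param sheet Sheet name or index (default first sheet).
#' @return A validated `"sw_trial"` data frame.
#' @export
read_oxtext_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("readxl is required to read XLSX workbooks", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  map_trial_frame(df)
}

#' Fit all nine formulations to one trial dataset
#'
#' Re-analysis mode: fits every formulation M1..M9 by maximum likelihood
#' under the requested covariance structure, extracts both
#' intervention-effect estimands with standard errors and p-values, and
#' reports the BIC of each fit — one report row per formulation. Models
#' that fail to converge are reported in-row (`converged = FALSE`) and the
#' run continues.
#'
#' @param dataset A validated trial data frame (simulated or read from
#'   disk).
#' @param structure `"CS"` or `"AR1"`.
#' @param ci_reference `"normal"` or `"t"`.
#' @param level Confidence level.
#' @return A data frame with columns `formulation`, `effect_6m`, `se_6m`,
#'   `p_6m`, `effect_avg`, `se_avg`, `p_avg`, `bic`, `converged`.
#' @export
reanalyze <- function(dataset, structure = c("CS", "AR1"),
                      ci_reference = c("normal", "t"), level = 0.95) {
  structure <- match.arg(structure)
  ci_reference <- match.arg(ci_reference)
  dataset <- validate_trial(as.data.frame(dataset))
  n <- trial_n_steps(dataset)
  rows <- lapply(paste0("M", 1:9), function(f) {
    fit <- tryCatch(fit_formulation(dataset, f, structure = structure),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(formulation = f, effect_6m = NA_real_,
                        se_6m = NA_real_, p_6m = NA_real_,
                        effect_avg = NA_real_, se_avg = NA_real_,
                        p_avg = NA_real_, bic = NA_real_, converged = FALSE))
    e6 <- estimate_effect(fit, contrast(f, "six_month", n), level = level,
                          reference = ci_reference, estimand = "six_month")
    ea <- estimate_effect(fit, contrast(f, "time_averaged", n), level = level,
                          reference = ci_reference, estimand = "time_averaged")
    data.frame(formulation = f, effect_6m = e6$estimate, se_6m = e6$se,
               p_6m = e6$p, effect_avg = ea$estimate, se_avg = ea$se,
               p_avg = ea$p, bic = fit$bic, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and validate a run configuration
#'
#' Configurations are flat YAML key-value files. Required keys:
#' `n_clusters`, `subjects_per_cluster`, `scenarios`, `formulations`,
#' `structures`, `n_reps`, `master_seed`. Optional: `level`,
#' `ci_reference`, `mse_mode`, `output`. `scenarios: all` expands to
#' D1..D36 and `formulations: all` to M1..M9.
#'
#' @param path Path to a YAML configuration file.
#' @param config A configuration list.
#' @return `read_config()` returns the raw list; `validate_config()`
#'   returns the list with defaults filled in, erroring on any unknown
#'   scenario/formulation/structure id before any computation.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  need <- c("n_clusters", "subjects_per_cluster", "scenarios", "formulations",
            "structures", "n_reps", "master_seed")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys))
    stop("config is missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  if (identical(config$scenarios, "all")) config$scenarios <- paste0("D", 1:36)
  if (identical(config$formulations, "all")) config$formulations <- paste0("M", 1:9)
  bad_sc <- setdiff(config$scenarios, paste0("D", 1:36))
  if (length(bad_sc))
    stop("unknown scenario id(s) in config: ", paste(bad_sc, collapse = ", "),
         call. = FALSE)
  bad_f <- setdiff(config$formulations, paste0("M", 1:9))
  if (length(bad_f))
    stop("unknown formulation id(s) in config: ", paste(bad_f, collapse = ", "),
         call. = FALSE)
  bad_st <- setdiff(config$structures, c("CS", "AR1"))
  if (length(bad_st))
    stop("unknown covariance structure(s) in config: ",
         paste(bad_st, collapse = ", "), call. = FALSE)
  config$level <- config$level %||% 0.95
  config$ci_reference <- config$ci_reference %||% "normal"
  config$mse_mode <- config$mse_mode %||% "conditional"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
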