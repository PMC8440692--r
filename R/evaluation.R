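#' Evaluation settings for replicated simulation studies
#'
#' @param eval_times Times (seconds) at which estimated SAT functions are
#'   compared to the truth; default the eight standard SOA levels.
#' @param precision_threshold Target function SD (probability correct) for
#'   the trials-to-precision comparison; default 0.02.
#' @param hwci_level Credible-interval coverage; default 0.682.
#' @param n_reps Number of replications.
#' @return An object of class `"eval_config"`.
#' @export
eval_config <- function(eval_times = c(0.06, 0.09, 0.12, 0.24, 0.36, 0.48,
                                       0.60, 1.20),
                        precision_threshold = 0.02,
                        hwci_level = 0.682,
                        n_reps = 200L) {
  stopifnot(length(eval_times) >= 1, precision_threshold > 0,
            hwci_level > 0, hwci_level <= 1, n_reps >= 1)
  structure(list(eval_times = eval_times,
                 precision_threshold = precision_threshold,
                 hwci_level = hwci_level, n_reps = as.integer(n_reps)),
            class = "eval_config")
}

#' Mean absolute error of parameter estimates over replications
#'
#' @param estimates Per-replication estimates at one checkpoint.
#' @param truth True parameter value.
#' @param na.rm Drop failed (NA) replications.
#' @return Mean absolute error; attribute `"n"` gives the replications used.
#' @export
param_bias <- function(estimates, truth, na.rm = TRUE) {
  if (na.rm) estimates <- estimates[!is.na(estimates)]
  structure(mean(abs(estimates - truth)), n = length(estimates))
}

#' Average absolute bias of estimated SAT functions
#'
#' The signed estimation errors are summed across replications within each
#' time point, the absolute value is taken per time point, and the result is
#' summed over time points and divided by (replications x time points) —
#' so errors of opposite sign cancel within a time point. The stricter
#' replication-wise mean absolute error is available as `type = "mae"`.
#'
#' @param curves J x K matrix of estimated probability correct (rows:
#'   replications, columns: evaluation times).
#' @param truth_curve Length-K true probability correct.
#' @param type `"signed"` (default, cancellation allowed) or `"mae"`.
#' @return Average absolute bias; attribute `"n"` gives the replications
#'   used (rows with any NA are dropped).
#' @export
function_bias <- function(curves, truth_curve, type = c("signed", "mae")) {
  type <- match.arg(type)
  curves <- as.matrix(curves)
  stopifnot(ncol(curves) == length(truth_curve))
  keep <- stats::complete.cases(curves)
  curves <- curves[keep, , drop = FALSE]
  J <- nrow(curves)
  if (J == 0L) return(structure(NA_real_, n = 0L))
  err <- sweep(curves, 2, truth_curve)
  v <- if (type == "signed") {
    sum(abs(colSums(err))) / (J * ncol(curves))
  } else {
    mean(rowMeans(abs(err)))
  }
  structure(v, n = J)
}

#' Pooled standard deviation of estimated SAT functions
#'
#' The square root of the average, over time points and replications, of the
#' squared deviation of each curve value from its per-time replication mean.
#'
#' @inheritParams function_bias
#' @return Pooled SD; attribute `"n"` gives the replications used.
#' @export
function_sd <- function(curves) {
  curves <- as.matrix(curves)
  keep <- stats::complete.cases(curves)
  curves <- curves[keep, , drop = FALSE]
  J <- nrow(curves)
  if (J == 0L) return(structure(NA_real_, n = 0L))
  dev <- sweep(curves, 2, colMeans(curves))
  structure(sqrt(sum(dev^2) / (J * ncol(curves))), n = J)
}

#' Trials required to reach a target function precision
#'
#' Locates the downward crossing of the SD trajectory through the threshold.
#' The Bayesian procedures start with near-zero dispersion (every replication
#' shares the same prior), rise, then fall, so the search starts at the
#' trajectory's maximum: the reported count is the first checkpoint after the
#' peak at which the SD is at or below the threshold, linearly interpolated
#' between the bracketing checkpoints. For monotone decreasing trajectories
#' (the non-Bayesian procedures) this is the plain first crossing. A
#' trajectory that is below threshold throughout reports the first
#' checkpoint; one that never falls below it after the peak reports `NA`
#' (not reached).
#'
#' @param checkpoints Trial counts (increasing).
#' @param sds Function SD at each checkpoint (NA checkpoints are dropped).
#' @param threshold Target SD; default 0.02.
#' @return Interpolated trial count, or `NA` if the threshold is not reached.
#' @examples
#' trials_to_precision(c(100, 300), c(0.03, 0.01), 0.02)  # 200
#' @export
trials_to_precision <- function(checkpoints, sds, threshold = 0.02) {
  stopifnot(length(checkpoints) == length(sds), threshold > 0)
  keep <- !is.na(sds)
  checkpoints <- checkpoints[keep]
  sds <- sds[keep]
  if (length(sds) == 0L) return(NA_real_)
  if (all(sds <= threshold)) return(as.numeric(checkpoints[1L]))
  peak <- which.max(sds)
  below <- which(sds <= threshold)
  below <- below[below > peak]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  t0 <- checkpoints[i - 1L]; t1 <- checkpoints[i]
  s0 <- sds[i - 1L]; s1 <- sds[i]
  as.numeric(t0 + (t1 - t0) * (s0 - threshold) / (s0 - s1))
}

#' Summarize a replicated simulation study
#'
#' Aggregates a list of [run_procedure()] results from identical
#' configurations into per-checkpoint accuracy and precision metrics:
#' parameter bias (mean absolute error) and SD per parameter, mean parameter
#' HWCIs (Bayesian routes), function average absolute bias ([function_bias()],
#' both variants), function SD ([function_sd()]), mean function HWCI, and the
#' trials-to-precision crossing.
#'
#' @param runs List of `sat_run` objects sharing checkpoints and eval times.
#' @param truth The generating [sat_params()] (or coercible).
#' @param cfg An [eval_config()]; its `eval_times` must match the runs'.
#' @param task A [task_spec()] for the true curve.
#' @return An object of class `"sat_eval"`: list with `summary` (tidy data
#'   frame: checkpoint, metric, value, n), `trials_to_precision`,
#'   `checkpoints`, `truth`.
#' @export
evaluate_runs <- function(runs, truth, cfg = eval_config(),
                          task = task_spec()) {
  stopifnot(length(runs) >= 1)
  truth <- as_sat_params(truth)
  cks <- runs[[1L]]$checkpoints
  times <- runs[[1L]]$cfg$eval_times
  if (!isTRUE(all.equal(times, cfg$eval_times)))
    stop("runs were recorded at different eval times than 'cfg'",
         call. = FALSE)
  truth_curve <- sat_pc(times, truth, task)
  nck <- length(cks)
  est <- array(NA_real_, c(length(runs), nck, 3))
  hw <- array(NA_real_, c(length(runs), nck, 3))
  fc <- array(NA_real_, c(length(runs), nck, length(times)))
  fh <- array(NA_real_, c(length(runs), nck, length(times)))
  for (j in seq_along(runs)) {
    r <- runs[[j]]
    if (!identical(r$checkpoints, cks))
      stop("runs have differing checkpoints", call. = FALSE)
    est[j, , ] <- r$estimates
    hw[j, , ] <- r$hwci
    fc[j, , ] <- r$fcurve
    fh[j, , ] <- r$fhwci
  }
  tru <- c(truth$lam, truth$gam, truth$delta)
  pname <- c("lam", "gam", "delta")
  rows <- list()
  add <- function(ck, metric, value, n)
    rows[[length(rows) + 1L]] <<- data.frame(checkpoint = ck,
                                             metric = metric,
                                             value = as.numeric(value),
                                             n = as.integer(n))
  sds <- numeric(nck)
  for (i in seq_len(nck)) {
    for (p in 1:3) {
      b <- param_bias(est[, i, p], tru[p])
      add(cks[i], paste0("bias_", pname[p]), b, attr(b, "n"))
      add(cks[i], paste0("sd_", pname[p]),
          stats::sd(est[, i, p][!is.na(est[, i, p])]), attr(b, "n"))
      mh <- mean(hw[, i, p], na.rm = TRUE)
      add(cks[i], paste0("hwci_", pname[p]), mh,
          sum(!is.na(hw[, i, p])))
    }
    fci <- matrix(fc[, i, ], ncol = length(times))
    fhi <- matrix(fh[, i, ], ncol = length(times))
    fb <- function_bias(fci, truth_curve)
    add(cks[i], "fbias", fb, attr(fb, "n"))
    fbm <- function_bias(fci, truth_curve, type = "mae")
    add(cks[i], "fbias_mae", fbm, attr(fbm, "n"))
    fs <- function_sd(fci)
    sds[i] <- fs
    add(cks[i], "fsd", fs, attr(fs, "n"))
    add(cks[i], "fhwci", mean(fhi, na.rm = TRUE),
        sum(stats::complete.cases(fhi)))
  }
  ttp <- trials_to_precision(cks, sds, cfg$precision_threshold)
  structure(list(summary = do.call(rbind, rows),
                 trials_to_precision = ttp,
                 checkpoints = cks,
                 eval_times = times,
                 truth = truth,
                 n_reps = length(runs)),
            class = "sat_eval")
}

#' @export
print.sat_eval <- function(x, ...) {
  cat(sprintf("Simulation study summary: %d replications, %d checkpoints\n",
              x$n_reps, length(x$checkpoints)))
  last <- max(x$checkpoints)
  s <- x$summary[x$summary$checkpoint == last, ]
  cat(sprintf("  at %d trials: ", last))
  for (m in c("bias_lam", "bias_gam", "bias_delta", "fbias", "fsd"))
    if (m %in% s$metric)
      cat(sprintf("%s=%.4g ", m, s$value[s$metric == m]))
  cat("\n")
  if (!is.na(x$trials_to_precision))
    cat(sprintf("  trials to reach target function SD: %.0f\n",
                x$trials_to_precision))
  invisible(x)
}

#' Extract one metric trajectory from a study summary
#'
#' @param eval A [evaluate_runs()] result.
#' @param metric Metric name as used in `eval$summary` (e.g. `"fsd"`,
#'   `"bias_lam"`, `"fbias"`, `"fhwci"`).
#' @return Named numeric vector over checkpoints.
#' @export
metric_trajectory <- function(eval, metric) {
  stopifnot(inherits(eval, "sat_eval"))
  s <- eval$summary[eval$summary$metric == metric, ]
  stats::setNames(s$value, s$checkpoint)
}
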