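#' Write / read trial data as CSV
#'
#' Plain CSV with header `soa,rt,correct,block_index`; times in seconds,
#' `correct` coded 0/1. `read_trials()` accepts files with or without the
#' `block_index` column and validates the schema, reporting offending rows.
#'
#' @param trials A trial data frame (`soa`, `rt`, `correct`, optional
#'   `block`).
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a
#'   trial data frame with columns `soa`, `rt`, `correct`, `block`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials),
            all(c("soa", "rt", "correct") %in% names(trials)))
  out <- data.frame(soa = trials$soa, rt = trials$rt,
                    correct = trials$correct,
                    block_index = if ("block" %in% names(trials))
                      trials$block else seq_len(nrow(trials)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  dat <- utils::read.csv(path)
  if (nrow(dat) == 0L) stop("empty trial file: ", path, call. = FALSE)
  miss <- setdiff(c("soa", "rt", "correct"), names(dat))
  if (length(miss))
    stop("trial file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("soa", "rt")) {
    if (!is.numeric(dat[[col]]))
      stop(sprintf("column '%s' is not numeric (first bad line: %d)", col,
                   which(is.na(suppressWarnings(as.numeric(dat[[col]]))))[1] + 1L),
           call. = FALSE)
  }
  bad <- which(!(dat$correct %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("column 'correct' must be 0/1; bad line(s): %s",
                 paste(utils::head(bad + 1L, 5L), collapse = ", ")),
         call. = FALSE)
  data.frame(soa = dat$soa, rt = dat$rt, correct = as.integer(dat$correct),
             block = if ("block_index" %in% names(dat))
               dat$block_index else seq_len(nrow(dat)))
}

#' Write the selection trace of an adaptive run
#'
#' CSV with columns `block_index`, `selected_soa`, `expected_gain` (nats),
#' `posterior_entropy` (nats) and `realized_gain` (nats).
#'
#' @param run A `sat_run` from the adaptive procedure.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(run, path) {
  if (is.null(run$selection))
    stop("run has no selection trace (not an adaptive run)", call. = FALSE)
  out <- data.frame(block_index = run$selection$block,
                    selected_soa = run$selection$soa,
                    expected_gain = run$selection$expected_gain,
                    posterior_entropy = run$selection$entropy,
                    realized_gain = run$selection$realized_gain)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic per-replication seed streams drawn once from the master seed
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a replicated simulation study for one observer and procedure
#'
#' Repeats [run_procedure()] `n_reps` times with per-replication seeds drawn
#' deterministically from `master_seed`, sharing one set of precomputed
#' selection tables across replications.
#'
#' @param observer A [virtual_observer()].
#' @param cfg A [procedure_config()] (its `seed` field is overridden per
#'   replication).
#' @param n_reps Number of replications.
#' @param master_seed Integer master seed.
#' @param grid,space As in [run_procedure()].
#' @param tables Optional [selection_tables()] reused across replications.
#' @return List of `sat_run` objects, with the seed vector attached as
#'   attribute `"seeds"`.
#' @export
run_study <- function(observer, cfg, n_reps = 200L, master_seed = 1L,
                      grid = sat_grid(), space = stimulus_space(),
                      tables = NULL) {
  seeds <- derive_seeds(master_seed, n_reps)
  if (cfg$procedure == 4L && is.null(tables))
    tables <- selection_tables(grid, observer$task, space,
                               block_design(cfg$block_length,
                                            observer$task$window))
  runs <- vector("list", n_reps)
  for (j in seq_len(n_reps)) {
    cfg$seed <- seeds[j]
    runs[[j]] <- run_procedure(observer, cfg, grid = grid, space = space,
                               tables = tables)
  }
  attr(runs, "seeds") <- seeds
  runs
}

#' Run a full multi-observer, multi-procedure experiment
#'
#' Orchestrates replicated studies over a grid of observers and procedures,
#' writes a tidy metric summary (CSV), per-study trials-to-precision values,
#' and a manifest (JSON) recording the configuration and every derived seed
#' so that outputs can be replayed bit-identically.
#'
#' The configuration may be a YAML file path or an equivalent nested list
#' with entries `observers` (list of `lam`, `gam`, `delta` and optionally
#' `rt_mu`, `rt_sigma`, `rt_tau`), `procedures` (list of
#' [procedure_config()] argument lists), `n_reps`, `master_seed`, and
#' optional `eval` ([eval_config()] arguments). A ready-made default
#' configuration ships with the package:
#' `system.file("extdata", "default-study.yaml", package = "satadapt")`.
#'
#' @param config YAML file path or configuration list.
#' @param output_dir Directory for `summary.csv`, `trials_to_precision.csv`
#'   and `manifest.json`; created if missing.
#' @param save_runs Also write per-run checkpoint estimate CSVs under
#'   `runs/`.
#' @return Invisibly, a list with `summary` (data frame over observer x
#'   procedure x checkpoint x metric), `trials_to_precision` and `manifest`.
#' @export
run_experiment <- function(config, output_dir, save_runs = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$observers),
            !is.null(config$procedures))
  n_reps <- as.integer(config$n_reps %||% 200L)
  master_seed <- as.integer(config$master_seed %||% 1L)
  eval_args <- config$eval %||% list()
  ecfg <- do.call(eval_config, c(eval_args, list(n_reps = n_reps)))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  observers <- lapply(config$observers, function(o) {
    virtual_observer(sat_params(o$lam, o$gam, o$delta),
                     rtdist = ex_gauss(o$rt_mu %||% 0.3,
                                       o$rt_sigma %||% 0.06,
                                       o$rt_tau %||% 0.08))
  })
  grid <- sat_grid()
  space <- stimulus_space()
  all_sum <- list()
  ttp <- list()
  manifest <- list(master_seed = master_seed, n_reps = n_reps,
                   config = config, studies = list())
  for (oi in seq_along(observers)) {
    obs <- observers[[oi]]
    for (pi in seq_along(config$procedures)) {
      pargs <- config$procedures[[pi]]
      cfg <- do.call(procedure_config, pargs)
      study_seed <- (master_seed + 7919L * oi + 104729L * pi) %%
        .Machine$integer.max
      runs <- run_study(obs, cfg, n_reps = n_reps,
                        master_seed = study_seed, grid = grid,
                        space = space)
      ev <- evaluate_runs(runs, obs$sat, ecfg, obs$task)
      s <- ev$summary
      s$observer <- oi
      s$procedure <- cfg$procedure
      all_sum[[length(all_sum) + 1L]] <- s
      ttp[[length(ttp) + 1L]] <- data.frame(observer = oi,
                                            procedure = cfg$procedure,
                                            trials = ev$trials_to_precision)
      manifest$studies[[length(manifest$studies) + 1L]] <-
        list(observer = oi, procedure = cfg$procedure,
             study_seed = study_seed, seeds = attr(runs, "seeds"))
      if (save_runs) {
        rdir <- file.path(output_dir, "runs")
        dir.create(rdir, showWarnings = FALSE)
        for (j in seq_along(runs)) {
          est <- cbind(checkpoint = runs[[j]]$checkpoints,
                       runs[[j]]$estimates)
          utils::write.csv(est,
                           file.path(rdir, sprintf("obs%d_proc%d_rep%03d.csv",
                                                   oi, cfg$procedure, j)),
                           row.names = FALSE)
        }
      }
    }
  }
  summary <- do.call(rbind, all_sum)
  ttp <- do.call(rbind, ttp)
  utils::write.csv(summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(ttp, file.path(output_dir, "trials_to_precision.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summary = summary, trials_to_precision = ttp,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit recorded trial data from a CSV file
#'
#' Offline interface for fitting the SAT model to experimental data stored
#' in the package's trial CSV format.
#'
#' @param path Trial CSV (see [read_trials()]).
#' @param method Fitting route: 1 or `"mean"` (SOA-averaged ML), 2 or
#'   `"trial"` (trial-wise ML), 3 or `"bayes"` (Bayesian grid).
#' @param task A [task_spec()].
#' @param rt_policy What to do with RTs outside `[soa, soa + window]`:
#'   `"error"` (default), `"warn-keep"`, or `"warn-drop"`.
#' @param times Times at which the fitted curve is reported.
#' @param ... Passed to [sat_fit()].
#' @return A [sat_fit()] object.
#' @export
fit_data <- function(path, method = 3,
                     task = task_spec(),
                     rt_policy = c("error", "warn-keep", "warn-drop"),
                     times = c(0.06, 0.09, 0.12, 0.24, 0.36, 0.48, 0.60,
                               1.20), ...) {
  rt_policy <- match.arg(rt_policy)
  if (is.numeric(method))
    method <- c("mean", "trial", "bayes")[method]
  method <- match.arg(method, c("mean", "trial", "bayes"))
  dat <- read_trials(path)
  dat <- validate_trials(dat, as_task_spec(task), rt_policy)
  sat_fit(dat, method = method, task = task, ...)
}
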