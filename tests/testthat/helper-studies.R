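# Replicated simulation studies shared by the acceptance-level tests.
# Built lazily and cached for the session: several test blocks read different
# metrics from the same study.

.studies <- new.env(parent = emptyenv())

study_cached <- function(key, build) {
  if (is.null(.studies[[key]])) .studies[[key]] <- build()
  .studies[[key]]
}

N_REPS <- 200L

# observer 1 under the Bayesian adaptive procedure, full 2048-trial runs
study_main <- function() {
  study_cached("main", function() {
    obs <- reference_observers(1)[[1]]
    tab <- study_tables(16L)
    cfg <- procedure_config(4)
    runs <- run_study(obs, cfg, n_reps = N_REPS, master_seed = 202601,
                      tables = tab)
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

study_tables <- function(bl) {
  study_cached(paste0("tables", bl), function() {
    selection_tables(design = block_design(bl))
  })
}

# observers 2-4 under the adaptive procedure, past the 100-trial checkpoint
study_obs100 <- function(i) {
  study_cached(paste0("obs100_", i), function() {
    obs <- reference_observers(i)[[1]]
    cfg <- procedure_config(4, total_trials = 112,
                            checkpoints = c(100, 112))
    runs <- run_study(obs, cfg, n_reps = N_REPS,
                      master_seed = 202610 + i, tables = study_tables(16L))
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

# observer 1 under conventional MCS + SOA-averaged ML fits (procedure 1)
study_p1 <- function() {
  study_cached("p1", function() {
    obs <- reference_observers(1)[[1]]
    cfg <- procedure_config(1, total_trials = 1024,
                            checkpoints = c(128, 256, 384, 512, 640, 768,
                                            1024))
    runs <- run_study(obs, cfg, n_reps = N_REPS, master_seed = 202620)
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

# observer 4 under the adaptive procedure with block-end checkpoints
study_obs4 <- function() {
  study_cached("obs4", function() {
    obs <- reference_observers(4)[[1]]
    cfg <- procedure_config(4, total_trials = 512,
                            checkpoints = c(seq(16, 256, 16),
                                            seq(288, 512, 32)))
    runs <- run_study(obs, cfg, n_reps = N_REPS, master_seed = 202630,
                      tables = study_tables(16L))
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

# observer 1 with shorter adaptive blocks
study_bl <- function(bl) {
  study_cached(paste0("bl", bl), function() {
    obs <- reference_observers(1)[[1]]
    cfg <- procedure_config(4, total_trials = 256, block_length = bl,
                            checkpoints = c(64, 128, 192, 256))
    runs <- run_study(obs, cfg, n_reps = N_REPS,
                      master_seed = 202640 + bl,
                      tables = study_tables(as.integer(bl)))
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

# observer 1 under procedures 2 and 3 (MCS data), small-sample checkpoints
study_proc <- function(p) {
  study_cached(paste0("proc", p), function() {
    obs <- reference_observers(1)[[1]]
    cfg <- procedure_config(p, total_trials = 512,
                            checkpoints = c(128, 256, 512))
    runs <- run_study(obs, cfg, n_reps = N_REPS, master_seed = 202650)
    list(runs = runs, ev = evaluate_runs(runs, obs$sat))
  })
}

# metric value at one checkpoint of a study evaluation
at_ck <- function(ev, metric, ck) {
  unname(metric_trajectory(ev, metric)[as.character(ck)])
}

# standard error of a mean-absolute-error metric over replications
mae_se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
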