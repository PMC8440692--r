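test_that("trial CSVs round-trip and are validated on read", {
  obs <- reference_observers(2)[[1]]
  set.seed(61)
  d <- simulate_trials(obs, soa = c(0.12, 0.48), n = 8)
  f <- tempfile(fileext = ".csv")
  write_trials(d, f)
  back <- read_trials(f)
  expect_equal(back$soa, d$soa)
  expect_equal(back$rt, d$rt, tolerance = 1e-12)
  expect_equal(back$correct, d$correct)
  expect_equal(back$block, d$block)
  # empty file
  writeLines("soa,rt,correct", f)
  expect_error(read_trials(f), "empty")
  # schema violations
  writeLines(c("soa,rt", "0.1,0.2"), f)
  expect_error(read_trials(f), "correct")
  writeLines(c("soa,rt,correct", "0.1,0.2,2"), f)
  expect_error(read_trials(f), "0/1")
  unlink(f)
})

test_that("selection traces are written for adaptive runs only", {
  obs <- reference_observers(1)[[1]]
  cfg <- procedure_config(4, total_trials = 32, checkpoints = 32,
                          n_resamples = 50, seed = 62)
  run <- run_procedure(obs, cfg)
  f <- tempfile(fileext = ".csv")
  write_selection_trace(run, f)
  tr <- utils::read.csv(f)
  expect_named(tr, c("block_index", "selected_soa", "expected_gain",
                     "posterior_entropy", "realized_gain"))
  expect_equal(nrow(tr), 2)
  cfg3 <- procedure_config(3, total_trials = 32, checkpoints = 32,
                           n_resamples = 50, seed = 62)
  expect_error(write_selection_trace(run_procedure(obs, cfg3), f),
               "adaptive")
  unlink(f)
})

test_that("replicated studies replay exactly from the master seed", {
  obs <- reference_observers(1)[[1]]
  cfg <- procedure_config(3, total_trials = 32, checkpoints = 32,
                          n_resamples = 50)
  r1 <- run_study(obs, cfg, n_reps = 2, master_seed = 7)
  r2 <- run_study(obs, cfg, n_reps = 2, master_seed = 7)
  expect_identical(lapply(r1, `[[`, "estimates"),
                   lapply(r2, `[[`, "estimates"))
  expect_identical(lapply(r1, `[[`, "trials"), lapply(r2, `[[`, "trials"))
  # different master seed, different data
  r3 <- run_study(obs, cfg, n_reps = 2, master_seed = 8)
  expect_false(identical(r1[[1]]$trials, r3[[1]]$trials))
})

test_that("the experiment driver writes summary, crossings and manifest", {
  config <- list(
    observers = list(list(lam = 0.47, gam = 7.5, delta = 0.28)),
    procedures = list(list(procedure = 3, total_trials = 32,
                           checkpoints = c(16, 32), n_resamples = 50),
                      list(procedure = 4, total_trials = 32,
                           checkpoints = c(16, 32), n_resamples = 50)),
    n_reps = 2,
    master_seed = 5)
  out1 <- file.path(tempdir(), "exp1")
  res <- run_experiment(config, out1)
  expect_true(file.exists(file.path(out1, "summary.csv")))
  expect_true(file.exists(file.path(out1, "trials_to_precision.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_setequal(unique(res$summary$procedure), c(3, 4))
  # bit-identical replay
  out2 <- file.path(tempdir(), "exp2")
  run_experiment(config, out2)
  expect_identical(readLines(file.path(out1, "summary.csv")),
                   readLines(file.path(out2, "summary.csv")))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the bundled study configuration parses and scales down", {
  f <- system.file("extdata", "default-study.yaml", package = "satadapt")
  expect_true(nzchar(f))
  config <- yaml::read_yaml(f)
  expect_length(config$observers, 4)
  expect_length(config$procedures, 4)
  expect_equal(config$procedures[[4]]$procedure, 4)
  # scaled-down smoke run through the YAML pathway
  config$observers <- config$observers[1]
  config$procedures <- list(list(procedure = 3, total_trials = 32,
                                 checkpoints = 32, n_resamples = 50))
  config$n_reps <- 1
  out <- file.path(tempdir(), "exp-yaml")
  res <- run_experiment(config, out)
  expect_equal(nrow(res$trials_to_precision), 1)
  unlink(out, recursive = TRUE)
})

test_that("offline CSV fitting recovers a simulated observer", {
  obs <- reference_observers(2)[[1]]
  set.seed(63)
  d <- simulate_trials(obs, soa = rep(times8, 16), n = 16)  # 2048 trials
  f <- tempfile(fileext = ".csv")
  write_trials(d, f)
  fit <- fit_data(f, method = 3)
  cf <- coef(fit)
  expect_lt(abs(cf[["lam"]] - 0.45), 0.03)
  expect_lt(abs(cf[["gam"]] - 5), 3)
  expect_lt(abs(cf[["delta"]] - 0.22), 0.03)
  # numeric and name method selection agree
  fit2 <- fit_data(f, method = "bayes")
  expect_equal(coef(fit2), cf)
  # out-of-window RTs: configurable policy
  d2 <- d
  d2$rt[1] <- d2$soa[1] + 0.5
  write_trials(d2, f)
  expect_error(fit_data(f, method = 3), "outside")
  expect_warning(fit3 <- fit_data(f, method = 3, rt_policy = "warn-drop"),
                 "outside")
  expect_equal(fit3$n_trials, nrow(d) - 1L)
  unlink(f)
})
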