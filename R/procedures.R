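#' Configuration of one simulated estimation procedure
#'
#' Describes a runnable simulated experiment for one of the four estimation
#' procedures:
#'
#' 1. Method of constant stimuli (MCS), model fitted to per-SOA mean RT and
#'    accuracy by maximum likelihood.
#' 2. MCS, model fitted to trial-wise RT and correctness by maximum
#'    likelihood.
#' 3. MCS, grid-based Bayesian estimation updated after every trial.
#' 4. Bayesian adaptive: each block's SOA maximizes the expected information
#'    gain, posterior updated after every trial.
#'
#' @param procedure Integer 1-4.
#' @param soa_levels SOA levels for MCS (procedures 1-3); default the eight
#'   levels 0.06, 0.09, 0.12, 0.24, 0.36, 0.48, 0.60, 1.20 s.
#' @param total_trials Total trials per run; default 2048 (256 per SOA level).
#' @param block_length Trials per block; default 16.
#' @param mcs_mode `"short"` presents the SOA levels as randomized
#'   `block_length`-trial blocks; `"long"` presents one long block per level
#'   in random order.
#' @param checkpoints Trial counts at which estimates are recorded; default
#'   the powers of two up to `total_trials` plus 100.
#' @param eval_times Times (seconds) at which the estimated SAT function is
#'   evaluated at each checkpoint; default the eight SOA levels.
#' @param n_resamples Posterior resamples for function reconstruction
#'   (Bayesian procedures).
#' @param seed Optional integer seed for the run.
#' @return An object of class `"procedure_config"`.
#' @export
procedure_config <- function(procedure,
                             soa_levels = c(0.06, 0.09, 0.12, 0.24, 0.36,
                                            0.48, 0.60, 1.20),
                             total_trials = 2048L,
                             block_length = 16L,
                             mcs_mode = c("short", "long"),
                             checkpoints = NULL,
                             eval_times = c(0.06, 0.09, 0.12, 0.24, 0.36,
                                            0.48, 0.60, 1.20),
                             n_resamples = 1000L,
                             seed = NULL) {
  stopifnot(procedure %in% 1:4, total_trials >= 1, block_length >= 1)
  mcs_mode <- match.arg(mcs_mode)
  if (is.null(checkpoints)) {
    checkpoints <- 2^(0:floor(log2(total_trials)))
    checkpoints <- sort(unique(c(checkpoints, 100L, total_trials)))
    checkpoints <- checkpoints[checkpoints <= total_trials]
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 1L) || any(checkpoints > total_trials))
    stop("checkpoints must lie in [1, total_trials]", call. = FALSE)
  structure(list(procedure = as.integer(procedure),
                 soa_levels = soa_levels,
                 total_trials = as.integer(total_trials),
                 block_length = as.integer(block_length),
                 mcs_mode = mcs_mode,
                 checkpoints = checkpoints,
                 eval_times = eval_times,
                 n_resamples = as.integer(n_resamples),
                 seed = seed),
            class = "procedure_config")
}

# randomized MCS block order: SOA levels appear as equally often as the
# trial count allows (exactly balanced when total_trials is a multiple of
# block_length x number of levels); a non-divisible total shortens the
# final block
mcs_block_soas <- function(cfg) {
  n_soa <- length(cfg$soa_levels)
  if (cfg$mcs_mode == "long") {
    reps <- cfg$total_trials %/% n_soa
    len <- rep(reps, n_soa)
    extra <- cfg$total_trials - reps * n_soa
    if (extra > 0) len[n_soa] <- len[n_soa] + extra
    return(list(soas = sample(cfg$soa_levels), len = len))
  }
  n_blocks <- ceiling(cfg$total_trials / cfg$block_length)
  base <- n_blocks %/% n_soa
  counts <- rep(base, n_soa)
  extra <- n_blocks - base * n_soa
  if (extra > 0) {
    bump <- sample.int(n_soa, extra)
    counts[bump] <- counts[bump] + 1L
  }
  soas <- sample(rep(cfg$soa_levels, counts))
  len <- rep(cfg$block_length, n_blocks)
  len[n_blocks] <- cfg$total_trials - cfg$block_length * (n_blocks - 1L)
  list(soas = soas, len = len)
}

#' Run one simulated estimation procedure
#'
#' Simulates a full run of the configured procedure for one virtual observer
#' and records, at every checkpoint, the parameter estimates, the per-
#' parameter HWCIs (Bayesian routes), and the estimated SAT function at the
#' evaluation times (posterior resampling for Bayesian routes, plug-in for
#' maximum-likelihood routes). For the adaptive procedure the per-block
#' selection trace (chosen SOA, expected gain, posterior entropy and realized
#' entropy reduction) is kept.
#'
#' @param observer A [virtual_observer()].
#' @param cfg A [procedure_config()].
#' @param grid A [sat_grid()] (Bayesian routes).
#' @param space A [stimulus_space()] (procedure 4).
#' @param tables Optional precomputed [selection_tables()]; built on the fly
#'   when missing. Pass explicitly when running many replications.
#' @return An object of class `"sat_run"` with components `trials`,
#'   `checkpoints`, `estimates` (checkpoints x 3), `hwci`, `fcurve`
#'   (checkpoints x eval times), `fhwci`, `selection`, `convergence`.
#' @examples
#' obs <- reference_observers(1)[[1]]
#' cfg <- procedure_config(3, total_trials = 128, seed = 1)
#' run <- run_procedure(obs, cfg)
#' run$estimates[nrow(run$estimates), ]
#' @export
run_procedure <- function(observer, cfg, grid = sat_grid(),
                          space = stimulus_space(), tables = NULL) {
  stopifnot(inherits(observer, "virtual_observer"),
            inherits(cfg, "procedure_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$procedure == 4L) {
    run_adaptive(observer, cfg, grid, space, tables)
  } else {
    run_mcs(observer, cfg, grid)
  }
}

new_run <- function(observer, cfg) {
  nc <- length(cfg$checkpoints)
  K <- length(cfg$eval_times)
  list(procedure = cfg$procedure,
       observer = observer,
       cfg = cfg,
       trials = NULL,
       checkpoints = cfg$checkpoints,
       estimates = matrix(NA_real_, nc, 3,
                          dimnames = list(NULL, c("lam", "gam", "delta"))),
       hwci = matrix(NA_real_, nc, 3,
                     dimnames = list(NULL, c("lam", "gam", "delta"))),
       fcurve = matrix(NA_real_, nc, K),
       fhwci = matrix(NA_real_, nc, K),
       selection = NULL,
       convergence = rep(NA_integer_, nc),
       n_fallback = 0L)
}

record_bayes <- function(run, i, post) {
  est <- posterior_mean(post)
  run$estimates[i, ] <- c(est$lam, est$gam, est$delta)
  run$hwci[i, ] <- vapply(c("lam", "gam", "delta"),
                          function(p) posterior_hwci(post, p)$half_width,
                          numeric(1))
  rec <- reconstruct_sat(post, run$cfg$eval_times,
                         n_resamples = run$cfg$n_resamples,
                         task = run$observer$task)
  run$fcurve[i, ] <- rec$pc
  run$fhwci[i, ] <- rec$hwci
  run$convergence[i] <- 0L
  run
}

run_mcs <- function(observer, cfg, grid) {
  run <- new_run(observer, cfg)
  blocks <- mcs_block_soas(cfg)
  # trial stream simulated block by block (one RNG stream, reproducible)
  trials <- simulate_trials(observer, blocks$soas, n = blocks$len)
  run$n_fallback <- attr(trials, "n_fallback")
  run$trials <- trials
  if (cfg$procedure == 3L) {
    post <- sat_prior(grid)
    prev <- 0L
    for (i in seq_along(cfg$checkpoints)) {
      ck <- cfg$checkpoints[i]
      if (ck > prev)
        post <- posterior_update(post, trials[(prev + 1L):ck, ],
                                 task = observer$task)
      prev <- ck
      run <- record_bayes(run, i, post)
    }
  } else {
    method <- if (cfg$procedure == 1L) "mean" else "trial"
    prev_par <- NULL
    for (i in seq_along(cfg$checkpoints)) {
      ck <- cfg$checkpoints[i]
      fit <- tryCatch(
        sat_fit(trials[seq_len(ck), ], method = method, task = observer$task,
                grid = grid, start = prev_par),
        satadapt_unidentifiable = function(e) NULL)
      if (!is.null(fit)) {
        run$estimates[i, ] <- fit$coefficients
        run$convergence[i] <- fit$convergence
        run$fcurve[i, ] <- predict(fit, times = cfg$eval_times)
        prev_par <- unname(fit$coefficients)
      }
    }
  }
  run
}

run_adaptive <- function(observer, cfg, grid, space, tables) {
  design <- block_design(cfg$block_length, observer$task$window)
  if (is.null(tables)) {
    tables <- selection_tables(grid, observer$task, space, design)
  } else {
    stopifnot(inherits(tables, "selection_tables"))
    if (tables$design$n_trials != cfg$block_length)
      stop("selection tables were built for a different block length",
           call. = FALSE)
  }
  n_blocks <- ceiling(cfg$total_trials / cfg$block_length)
  run <- new_run(observer, cfg)
  post <- sat_prior(grid)
  sel <- data.frame(block = seq_len(n_blocks), soa = NA_real_,
                    expected_gain = NA_real_, entropy = NA_real_,
                    realized_gain = NA_real_)
  trials <- vector("list", n_blocks)
  done <- 0L
  ck_idx <- 1L
  nck <- length(cfg$checkpoints)
  for (b in seq_len(n_blocks)) {
    n_this <- min(cfg$block_length, cfg$total_trials - done)
    soa <- select_soa(post, tables)
    h0 <- posterior_entropy(post)
    sel$soa[b] <- as.numeric(soa)
    sel$expected_gain[b] <- attr(soa, "gain")[attr(soa, "index")]
    sel$entropy[b] <- h0
    blk <- simulate_block(observer, as.numeric(soa), n = n_this, block = b)
    run$n_fallback <- run$n_fallback + attr(blk, "n_fallback")
    trials[[b]] <- blk
    # absorb the block trial by trial, pausing at checkpoints
    pos <- 0L
    while (pos < n_this) {
      nxt <- if (ck_idx <= nck) cfg$checkpoints[ck_idx] - done - pos
             else n_this - pos
      take <- min(max(nxt, 1L), n_this - pos)
      post <- posterior_update(post, blk[(pos + 1L):(pos + take), ],
                               task = observer$task)
      pos <- pos + take
      if (ck_idx <= nck && done + pos == cfg$checkpoints[ck_idx]) {
        run <- record_bayes(run, ck_idx, post)
        ck_idx <- ck_idx + 1L
      }
    }
    done <- done + n_this
    sel$realized_gain[b] <- h0 - posterior_entropy(post)
  }
  run$trials <- do.call(rbind, trials)
  attr(run$trials, "n_fallback") <- run$n_fallback
  run$selection <- sel
  run
}

#' @export
print.sat_run <- function(x, ...) {
  cat(sprintf("Simulated run: procedure %d, %d trials, %d checkpoints\n",
              x$procedure, nrow(x$trials), length(x$checkpoints)))
  last <- max(which(!is.na(x$estimates[, 1])), 0L)
  if (last > 0L)
    cat(sprintf("  final estimate (at %d trials): lam %.4g, gam %.4g, delta %.4g\n",
                x$checkpoints[last], x$estimates[last, 1],
                x$estimates[last, 2], x$estimates[last, 3]))
  if (!is.null(x$selection))
    cat(sprintf("  %d adaptive blocks, mean realized gain %.4g nats\n",
                nrow(x$selection), mean(x$selection$realized_gain)))
  invisible(x)
}
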