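#' Fit the SAT function to response-signal trial data
#'
#' Central fitting interface of the package. Three routes are supported, all
#' estimating the exponential-approach SAT model from (`soa`, `rt`, `correct`)
#' trial records:
#'
#' * `"bayes"` (default): grid-based Bayesian estimation. Trials are absorbed
#'   one by one into a posterior over a rectangular (lam, gam, delta) grid
#'   starting from a uniform prior; the estimate is the marginal posterior
#'   mean, and precision is reported as the half-width of the shortest 68.2%
#'   credible interval (HWCI) per parameter.
#' * `"trial"`: maximum-likelihood fit of the per-trial Bernoulli likelihood
#'   at each realized RT (no averaging).
#' * `"mean"`: the conventional route; trials are aggregated per SOA into a
#'   mean RT and a correct count, and the binomial likelihood at the per-SOA
#'   mean RTs is maximized.
#'
#' Maximum-likelihood routes run bounded (`L-BFGS-B`) optimization from
#' `n_starts` Latin-hypercube starting points inside `bounds` and keep the
#' best solution. With `objective = "lse"` the trial/mean routes instead
#' minimize squared accuracy residuals.
#'
#' @param data A data frame with numeric columns `soa`, `rt` (seconds) and
#'   `correct` (0/1). `rt` must lie in `[soa, soa + window]`.
#' @param method `"bayes"`, `"trial"` or `"mean"`.
#' @param task A [task_spec()].
#' @param grid A [sat_grid()] (Bayesian route).
#' @param objective `"mle"` (default) or `"lse"` (trial/mean routes only).
#' @param bounds 2 x 3 matrix of lower/upper bounds for (lam, gam, delta);
#'   defaults to the grid's axis ranges.
#' @param n_starts Number of Latin-hypercube restarts for ML fitting.
#' @param start Optional extra starting point(s), rows of (lam, gam, delta).
#' @param level Credible-interval coverage for the Bayesian route.
#' @return An object of class `"sat_fit"` with components `coefficients`
#'   (named lam, gam, delta), `method`, `task`, `data`, `n_trials`, and for
#'   the Bayesian route `posterior` and `hwci`; for ML routes `logLik`,
#'   `objective` and `convergence`. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()`,
#'   `simulate()` and `logLik()`.
#' @examples
#' obs <- reference_observers(1)[[1]]
#' set.seed(7)
#' dat <- simulate_trials(obs, soa = rep(c(0.06, 0.12, 0.36, 0.6, 1.2), 8),
#'                        n = 16)
#' fit <- sat_fit(dat, method = "bayes")
#' coef(fit)
#' predict(fit, times = c(0.3, 0.5, 1.0))
#' @export
sat_fit <- function(data,
                    method = c("bayes", "trial", "mean"),
                    task = task_spec(),
                    grid = sat_grid(),
                    objective = c("mle", "lse"),
                    bounds = NULL,
                    n_starts = 8L,
                    start = NULL,
                    level = 0.682) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  task <- as_task_spec(task)
  data <- validate_trials(data, task)
  if (is.null(bounds))
    bounds <- rbind(lower = c(min(grid$lam_axis), min(grid$gam_axis),
                              min(grid$del_axis)),
                    upper = c(max(grid$lam_axis), max(grid$gam_axis),
                              max(grid$del_axis)))
  out <- switch(method,
    bayes = fit_bayes(data, task, grid, level),
    trial = fit_ml(data, task, bounds, n_starts, start, objective,
                   aggregate = FALSE),
    mean  = fit_ml(data, task, bounds, n_starts, start, objective,
                   aggregate = TRUE))
  out$method <- method
  out$task <- task
  out$data <- data
  out$n_trials <- nrow(data)
  out$call <- match.call()
  class(out) <- "sat_fit"
  out
}

# schema checks shared by sat_fit and the offline file interface
validate_trials <- function(data, task, rt_policy = c("error", "warn-keep",
                                                      "warn-drop")) {
  rt_policy <- match.arg(rt_policy)
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("'data' must be a non-empty data frame", call. = FALSE)
  miss <- setdiff(c("soa", "rt", "correct"), names(data))
  if (length(miss))
    stop("'data' lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(data$correct %in% c(0, 1)))
    stop("'correct' must contain only 0/1 values", call. = FALSE)
  bad <- which(data$rt < data$soa - 1e-9 |
                 data$rt > data$soa + task$window + 1e-9)
  if (length(bad)) {
    msg <- sprintf("%d trial(s) with rt outside [soa, soa + window] (rows %s)",
                   length(bad),
                   paste(utils::head(bad, 5L), collapse = ", "))
    if (rt_policy == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    if (rt_policy == "warn-drop") data <- data[-bad, , drop = FALSE]
  }
  data
}

unidentifiable <- function(msg) {
  stop(errorCondition(msg, class = c("satadapt_unidentifiable", "error")))
}

fit_bayes <- function(data, task, grid, level) {
  post <- posterior_update(sat_prior(grid), data, task = task)
  est <- posterior_mean(post)
  hw <- vapply(c("lam", "gam", "delta"),
               function(p) posterior_hwci(post, p, level)$half_width,
               numeric(1))
  list(coefficients = c(lam = est$lam, gam = est$gam, delta = est$delta),
       posterior = post, hwci = hw, level = level)
}

# robust pc / (1 - pc) at times t for candidate parameters; branchless so the
# optimizer objective stays cheap
pc_q_vec <- function(t, par, chance) {
  lam <- par[1]; gam <- par[2]; del <- par[3]
  above <- (t > del)
  e <- exp(-gam * pmax(t - del, 0))
  # q computed without 1 - pc cancellation: stays positive even where pc
  # rounds to 1 (lam = 0.5, long RT)
  q <- rep(1 - chance, length(t))
  q[above] <- (1 - chance - lam) + lam * e[above]
  list(pc = chance + lam * (1 - e) * above, q = q)
}

fit_ml <- function(data, task, bounds, n_starts, start, objective, aggregate) {
  if (aggregate) {
    grp <- split(data, data$soa)
    if (length(grp) < 3L)
      unidentifiable("need data at >= 3 distinct SOAs to fit 3 parameters")
    mrt <- vapply(grp, function(d) mean(d$rt), numeric(1))
    kcor <- vapply(grp, function(d) sum(d$correct), numeric(1))
    ntr <- vapply(grp, nrow, numeric(1))
    objfun <- if (objective == "mle") {
      function(par) {
        pq <- pc_q_vec(mrt, par, task$chance)
        -sum(kcor * log(pq$pc) + (ntr - kcor) * log(pq$q))
      }
    } else {
      function(par) {
        pq <- pc_q_vec(mrt, par, task$chance)
        sum((kcor / ntr - pq$pc)^2)
      }
    }
  } else {
    if (length(unique(data$rt)) < 3L)
      unidentifiable("need >= 3 distinct RTs to fit 3 parameters")
    rt <- data$rt
    corr <- data$correct
    objfun <- if (objective == "mle") {
      function(par) {
        pq <- pc_q_vec(rt, par, task$chance)
        -sum(ifelse(corr == 1, log(pq$pc), log(pq$q)))
      }
    } else {
      function(par) {
        pq <- pc_q_vec(rt, par, task$chance)
        sum((corr - pq$pc)^2)
      }
    }
  }
  sol <- mle_fit(objfun, bounds, n_starts, start)
  list(coefficients = c(lam = sol$par[1], gam = sol$par[2],
                        delta = sol$par[3]),
       logLik = if (objective == "mle") -sol$value else NA_real_,
       objective = objective,
       convergence = sol$convergence)
}

#' Bounded multi-start minimization for SAT model fitting
#'
#' Minimizes an objective over (lam, gam, delta) inside box bounds with
#' `L-BFGS-B` from Latin-hypercube starting points (plus any user-supplied
#' starts), returning the best converged solution.
#'
#' @param objfun Function of a length-3 parameter vector.
#' @param bounds 2 x 3 matrix (rows: lower, upper).
#' @param n_starts Number of Latin-hypercube starts.
#' @param start Optional matrix (or vector) of extra starting points.
#' @return List with `par`, `value`, `convergence` (0 = at least one start
#'   converged) and `n_starts`.
#' @export
mle_fit <- function(objfun, bounds, n_starts = 8L, start = NULL) {
  lower <- bounds[1, ]; upper <- bounds[2, ]
  starts <- lhs::randomLHS(n_starts, 3L)
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(start)) {
    start <- matrix(start, ncol = 3L)
    start <- pmin(pmax(start, rep(lower, each = nrow(start))),
                  rep(upper, each = nrow(start)))
    starts <- rbind(start, starts)
  }
  best <- NULL
  conv <- 1L
  for (i in seq_len(nrow(starts))) {
    sol <- tryCatch(
      stats::optim(starts[i, ], objfun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e3, maxit = 500,
                                  ndeps = rep(1e-6, 3L))),
      error = function(e) NULL)
    if (is.null(sol)) next
    if (sol$convergence == 0L) conv <- 0L
    if (is.null(best) || sol$value < best$value) best <- sol
  }
  if (is.null(best))
    unidentifiable("all optimizer starts failed")
  list(par = unname(best$par), value = best$value, convergence = conv,
       n_starts = nrow(starts))
}
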