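#' Parameter grid for grid-based Bayesian SAT estimation
#'
#' A rectangular grid over (lam, gam, delta). The default axes are the ones
#' used throughout the simulation study: 21 linearly spaced lam values on
#' `[0.4, 0.5]`, 30 gam values on `[1, 30]` 1/s and 25 delta values on
#' `[0.02, 0.5]` s.
#'
#' @param lam,gam,delta Strictly increasing numeric axes.
#' @return An object of class `"sat_grid"` carrying the axes and the expanded
#'   per-cell parameter vectors (lam varying fastest, then gam, then delta).
#' @export
sat_grid <- function(lam = seq(0.4, 0.5, length.out = 21),
                     gam = seq(1, 30, length.out = 30),
                     delta = seq(0.02, 0.5, length.out = 25)) {
  for (ax in list(lam, gam, delta))
    if (length(ax) < 1L || is.unsorted(ax, strictly = TRUE))
      stop("grid axes must be strictly increasing", call. = FALSE)
  if (min(lam) <= 0 || max(lam) > 0.5)
    stop("'lam' axis must lie in (0, 0.5]", call. = FALSE)
  if (min(gam) <= 0) stop("'gam' axis must be positive", call. = FALSE)
  if (min(delta) < 0) stop("'delta' axis must be non-negative", call. = FALSE)
  cells <- expand.grid(lam = lam, gam = gam, delta = delta,
                       KEEP.OUT.ATTRS = FALSE)
  structure(list(lam_axis = lam, gam_axis = gam, del_axis = delta,
                 lam = cells$lam, gam = cells$gam, del = cells$delta,
                 dim = c(length(lam), length(gam), length(delta))),
            class = "sat_grid")
}

#' @export
print.sat_grid <- function(x, ...) {
  cat(sprintf("SAT parameter grid: %d x %d x %d (lam x gam x delta) = %d cells\n",
              x$dim[1], x$dim[2], x$dim[3], prod(x$dim)))
  invisible(x)
}

#' Uniform prior over a parameter grid
#'
#' @param grid A [sat_grid()].
#' @return An object of class `"sat_posterior"`: the grid plus a normalized
#'   weight vector `w` (equal mass per cell).
#' @export
sat_prior <- function(grid = sat_grid()) {
  stopifnot(inherits(grid, "sat_grid"))
  m <- prod(grid$dim)
  structure(list(grid = grid, w = rep(1 / m, m), n_trials = 0L),
            class = "sat_posterior")
}

#' @export
print.sat_posterior <- function(x, ...) {
  est <- posterior_mean(x)
  cat(sprintf("SAT grid posterior (%d cells, %d trials absorbed)\n",
              length(x$w), x$n_trials))
  cat(sprintf("  marginal means: lam = %.4g, gam = %.4g, delta = %.4g\n",
              est$lam, est$gam, est$delta))
  cat(sprintf("  entropy: %.4g nats\n", posterior_entropy(x)))
  invisible(x)
}

#' Per-cell likelihood of one trial
#'
#' For every grid cell, the probability of the observed response: probability
#' correct at the realized RT for a correct response, its complement for an
#' incorrect one.
#'
#' @param grid A [sat_grid()].
#' @param rt Realized response time, seconds.
#' @param correct 0/1 response.
#' @param task A [task_spec()].
#' @return Numeric vector over grid cells, values in (0, 1).
#' @export
trial_likelihood <- function(grid, rt, correct, task = task_spec()) {
  stopifnot(inherits(grid, "sat_grid"), rt >= 0, correct %in% c(0, 1))
  task <- as_task_spec(task)
  grid_likelihood_cpp(grid$lam, grid$gam, grid$del, task$chance,
                      rt, as.integer(correct))
}

#' Bayes update of a grid posterior
#'
#' Absorbs one or more trials sequentially: pointwise prior times likelihood,
#' renormalized after every trial. The input posterior is not modified.
#'
#' @param post A [sat_prior()]/`sat_posterior` object.
#' @param rt Response time(s), seconds, or a data frame with columns `rt` and
#'   `correct`.
#' @param correct 0/1 response(s), ignored when `rt` is a data frame.
#' @param task A [task_spec()].
#' @return The updated `sat_posterior`.
#' @export
posterior_update <- function(post, rt, correct = NULL, task = task_spec()) {
  stopifnot(inherits(post, "sat_posterior"))
  if (is.data.frame(rt)) {
    correct <- rt$correct
    rt <- rt$rt
  }
  stopifnot(length(rt) == length(correct), all(rt >= 0),
            all(correct %in% c(0, 1)))
  task <- as_task_spec(task)
  g <- post$grid
  post$w <- grid_update_cpp(post$w, g$lam, g$gam, g$del, task$chance,
                            as.numeric(rt), as.integer(correct))
  post$n_trials <- post$n_trials + length(rt)
  post
}

#' Marginal posterior over one parameter axis
#'
#' Collapses the 3-D grid posterior onto a single axis by summation over the
#' other two.
#'
#' @param post A `sat_posterior`.
#' @param param One of `"lam"`, `"gam"`, `"delta"`.
#' @return A data frame with columns `value` (axis points) and `mass`
#'   (sums to 1).
#' @export
posterior_marginal <- function(post, param = c("lam", "gam", "delta")) {
  param <- match.arg(param)
  a <- array(post$w, dim = post$grid$dim)
  switch(param,
    lam = data.frame(value = post$grid$lam_axis, mass = rowSums(a, dims = 1)),
    gam = data.frame(value = post$grid$gam_axis,
                     mass = rowSums(colSums(a, dims = 1))),
    delta = data.frame(value = post$grid$del_axis,
                       mass = as.vector(colSums(a, dims = 2))))
}

#' Posterior-mean SAT parameter estimate
#'
#' The marginal mean of each parameter axis; the running estimate reported
#' after every trial by the Bayesian procedures.
#'
#' @param post A `sat_posterior`.
#' @return A [sat_params()] object.
#' @export
posterior_mean <- function(post) {
  stopifnot(inherits(post, "sat_posterior"))
  sat_params(sum(post$w * post$grid$lam),
             sum(post$w * post$grid$gam),
             sum(post$w * post$grid$del))
}

#' Shannon entropy of a grid posterior
#'
#' @param post A `sat_posterior`.
#' @return Entropy in nats (`0 log 0` taken as 0).
#' @export
posterior_entropy <- function(post) {
  w <- post$w[post$w > 0]
  -sum(w * log(w))
}

#' Shortest credible interval on a discrete marginal
#'
#' The shortest contiguous run of grid points whose cumulative mass reaches
#' `level`; ties break toward the narrower window, then toward the smaller
#' lower bound. The half-width of this interval (HWCI) is the precision
#' measure used throughout.
#'
#' @param mass Probability mass per axis point (sums to 1).
#' @param values Axis points, strictly increasing, same length as `mass`.
#' @param level Coverage fraction, default 0.682.
#' @return An object of class `"credible_interval"`: list with `level`,
#'   `lower`, `upper`, `half_width`.
#' @examples
#' hwci_mass(rep(1/21, 21), seq(0.4, 0.5, length.out = 21))  # half-width 0.035
#' @export
hwci_mass <- function(mass, values, level = 0.682) {
  stopifnot(length(mass) == length(values), all(mass >= 0),
            level > 0, level <= 1)
  n <- length(mass)
  cs <- c(0, cumsum(mass))
  tot <- cs[n + 1L]
  for (L in seq_len(n)) {
    win <- cs[(L + 1L):(n + 1L)] - cs[seq_len(n - L + 1L)]
    hit <- which(win >= level * tot - 1e-12)
    if (length(hit)) {
      i <- hit[1L]
      lo <- values[i]; hi <- values[i + L - 1L]
      return(structure(list(level = level, lower = lo, upper = hi,
                            half_width = (hi - lo) / 2),
                       class = "credible_interval"))
    }
  }
  structure(list(level = level, lower = values[1L], upper = values[n],
                 half_width = (values[n] - values[1L]) / 2),
            class = "credible_interval")
}

#' @export
print.credible_interval <- function(x, ...) {
  cat(sprintf("%.1f%% credible interval: [%.4g, %.4g], half-width %.4g\n",
              100 * x$level, x$lower, x$upper, x$half_width))
  invisible(x)
}

#' Shortest credible interval of a posterior marginal
#'
#' @inheritParams posterior_marginal
#' @param level Coverage fraction, default 0.682.
#' @return A `"credible_interval"` (see [hwci_mass()]).
#' @export
posterior_hwci <- function(post, param = c("lam", "gam", "delta"),
                           level = 0.682) {
  m <- posterior_marginal(post, param)
  hwci_mass(m$mass, m$value, level)
}

# shortest interval containing ceil(level * n) of the sampled values
hwci_sample <- function(x, level = 0.682) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(level * n)
  if (m >= n) return((x[n] - x[1L]) / 2)
  widths <- x[m:n] - x[1:(n - m + 1L)]
  min(widths) / 2
}

# inverse-CDF resampling of grid cells proportional to posterior mass
resample_cells <- function(post, n) {
  cw <- cumsum(post$w)
  cw <- cw / cw[length(cw)]
  findInterval(stats::runif(n), cw) + 1L
}

#' Exact posterior-mixture SAT curve
#'
#' The posterior-weighted average of the probability-correct curve,
#' \eqn{\sum_\theta p(\theta)\, pc_\theta(t)}, the limit of the resampling
#' reconstruction as the number of resamples grows.
#'
#' @param post A `sat_posterior`.
#' @param times Evaluation times, seconds.
#' @param task A [task_spec()].
#' @return Numeric vector of probability correct at `times`.
#' @export
posterior_mean_curve <- function(post, times, task = task_spec()) {
  task <- as_task_spec(task)
  g <- post$grid
  vapply(times, function(t) {
    psi <- ifelse(t > g$del, g$lam * (1 - exp(-g$gam * pmax(t - g$del, 0))), 0)
    task$chance + sum(post$w * psi)
  }, numeric(1))
}

#' Reconstruct the SAT function from a posterior by resampling
#'
#' Draws parameter triples from the posterior (with replacement, proportional
#' to mass), evaluates each sampled SAT curve at `times`, and averages.
#' The spread of the resampled curve values at each time is summarized by the
#' shortest 68.2% interval's half-width.
#'
#' @param post A `sat_posterior`.
#' @param times Evaluation times, seconds.
#' @param n_resamples Number of posterior draws, default 1000.
#' @param level Coverage fraction of the reported spread.
#' @param task A [task_spec()].
#' @return A data frame with columns `time`, `pc` (resampled mean probability
#'   correct), `hwci`, `lower`, `upper`.
#' @export
reconstruct_sat <- function(post, times, n_resamples = 1000L, level = 0.682,
                            task = task_spec()) {
  stopifnot(n_resamples >= 1)
  task <- as_task_spec(task)
  g <- post$grid
  idx <- resample_cells(post, n_resamples)
  lam <- g$lam[idx]; gam <- g$gam[idx]; del <- g$del[idx]
  out <- lapply(times, function(t) {
    psi <- ifelse(t > del, lam * (1 - exp(-gam * pmax(t - del, 0))), 0)
    pc <- task$chance + psi
    x <- sort(pc)
    n <- length(x)
    m <- ceiling(level * n)
    if (m >= n) {
      lo <- x[1L]; hi <- x[n]
    } else {
      i <- which.min(x[m:n] - x[1:(n - m + 1L)])
      lo <- x[i]; hi <- x[i + m - 1L]
    }
    c(mean(pc), (hi - lo) / 2, lo, hi)
  })
  out <- do.call(rbind, out)
  data.frame(time = times, pc = out[, 1], hwci = out[, 2],
             lower = out[, 3], upper = out[, 4])
}

#' Write / read a posterior snapshot as JSON
#'
#' The snapshot stores the three axes and the flat mass array (lam varying
#' fastest, then gam, then delta) plus a schema version.
#'
#' @param post A `sat_posterior`.
#' @param path Output file path.
#' @return `write_posterior()` returns `path` invisibly; `read_posterior()`
#'   returns a `sat_posterior`.
#' @export
write_posterior <- function(post, path) {
  stopifnot(inherits(post, "sat_posterior"))
  obj <- list(schema = "satadapt-posterior-1",
              lam_axis = post$grid$lam_axis,
              gam_axis = post$grid$gam_axis,
              del_axis = post$grid$del_axis,
              n_trials = post$n_trials,
              mass = post$w)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "satadapt-posterior-1"))
    stop("not a satadapt posterior snapshot", call. = FALSE)
  g <- sat_grid(obj$lam_axis, obj$gam_axis, obj$del_axis)
  w <- as.numeric(obj$mass)
  if (length(w) != prod(g$dim)) stop("mass length mismatch", call. = FALSE)
  structure(list(grid = g, w = w / sum(w),
                 n_trials = as.integer(obj$n_trials)),
            class = "sat_posterior")
}
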