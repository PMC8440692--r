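#' SAT model parameters
#'
#' Construct and validate the parameter triple of the exponential-approach
#' speed-accuracy tradeoff (SAT) function. Accuracy above chance rises from the
#' x-intercept `delta` towards the asymptote `lam` at rate `gam`:
#' \deqn{\Psi(t) = \lambda (1 - e^{-\gamma (t - \delta)}) \quad (t > \delta),
#'       \qquad \Psi(t) = 0 \quad (t \le \delta).}
#'
#' `lam` is the *above-chance* asymptote, so for a two-alternative forced
#' choice task total asymptotic accuracy is `chance + lam`.
#'
#' @param lam Asymptotic above-chance accuracy, in probability units;
#'   `0 < lam <= 0.5` so that `chance + lam <= 1` for 2AFC.
#' @param gam Rate of rise, in 1/seconds; must be positive.
#' @param delta Intercept, in seconds, below which performance is at chance;
#'   must be non-negative.
#' @return An object of class `"sat_params"`: a named list with elements
#'   `lam`, `gam`, `delta`.
#' @examples
#' p <- sat_params(0.47, 7.5, 0.28)
#' sat_psi(c(0.28, 0.7, 5), p)
#' @export
sat_params <- function(lam, gam, delta) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(gam), length(gam) == 1L, is.finite(gam),
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (lam <= 0 || lam > 0.5)
    stop("'lam' must lie in (0, 0.5]", call. = FALSE)
  if (gam <= 0) stop("'gam' must be positive", call. = FALSE)
  if (delta < 0) stop("'delta' must be non-negative", call. = FALSE)
  structure(list(lam = lam, gam = gam, delta = delta), class = "sat_params")
}

#' @export
print.sat_params <- function(x, ...) {
  cat(sprintf("SAT parameters: lam = %.4g, gam = %.4g 1/s, delta = %.4g s\n",
              x$lam, x$gam, x$delta))
  invisible(x)
}

#' Task specification for a response-signal experiment
#'
#' The task-level constants shared by simulation and fitting: the guessing
#' probability and the length of the response window that follows the response
#' signal. The chance level is the y-offset at which accuracy starts to rise.
#'
#' @param chance Guessing probability (0.5 for 2AFC); in `[0, 1)`.
#' @param window Response window length in seconds; positive.
#' @return An object of class `"task_spec"`.
#' @examples
#' task_spec()           # 2AFC, 0.2 s window
#' @export
task_spec <- function(chance = 0.5, window = 0.2) {
  stopifnot(is.numeric(chance), length(chance) == 1L, is.finite(chance),
            is.numeric(window), length(window) == 1L, is.finite(window))
  if (chance < 0 || chance >= 1)
    stop("'chance' must lie in [0, 1)", call. = FALSE)
  if (window <= 0) stop("'window' must be positive", call. = FALSE)
  structure(list(chance = chance, window = window), class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("Task: chance = %.3g, response window = %.3g s\n",
              x$chance, x$window))
  invisible(x)
}

#' Above-chance accuracy of the SAT function
#'
#' Evaluates the exponential-approach SAT curve, i.e. accuracy in excess of
#' chance, at response times `t`. Returns 0 for `t <= delta` (the piecewise
#' branch includes the intercept itself).
#'
#' @param t Response times in seconds (vectorized); non-negative.
#' @param params A [sat_params()] object.
#' @return Above-chance accuracy in `[0, lam]`, same length as `t`.
#' @seealso [sat_pc()] for total probability correct.
#' @export
sat_psi <- function(t, params) {
  params <- as_sat_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)), all(t >= 0))
  ifelse(t > params$delta,
         params$lam * (1 - exp(-params$gam * (t - params$delta))),
         0)
}

#' Probability correct of the SAT function
#'
#' Total probability of a correct response at response time `t`:
#' `chance + sat_psi(t, params)`. This single mapping is used both to simulate
#' observers and as the likelihood in every fitting route.
#'
#' @inheritParams sat_psi
#' @param task A [task_spec()] object supplying the chance level.
#' @return Probability correct in `[chance, chance + lam]`.
#' @examples
#' sat_pc(0.7, sat_params(0.47, 7.5, 0.28), task_spec())  # 0.9499
#' @export
sat_pc <- function(t, params, task = task_spec()) {
  task <- as_task_spec(task)
  task$chance + sat_psi(t, params)
}

# coercion helpers: accept a ready object or a plain list with the same fields
as_sat_params <- function(x) {
  if (inherits(x, "sat_params")) return(x)
  if (is.list(x) && all(c("lam", "gam", "delta") %in% names(x)))
    return(sat_params(x$lam, x$gam, x$delta))
  if (is.numeric(x) && length(x) == 3L)
    return(sat_params(x[[1L]], x[[2L]], x[[3L]]))
  stop("cannot interpret 'params' as SAT parameters", call. = FALSE)
}

as_task_spec <- function(x) {
  if (inherits(x, "task_spec")) return(x)
  if (is.list(x) && all(c("chance", "window") %in% names(x)))
    return(task_spec(x$chance, x$window))
  stop("cannot interpret 'task' as a task specification", call. = FALSE)
}
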