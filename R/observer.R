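#' Ex-Gaussian response-time distribution parameters
#'
#' Parameters of the ex-Gaussian (Gaussian plus independent exponential)
#' response-time distribution used by the virtual observers. The untruncated
#' mean is `mu + tau`.
#'
#' @param mu Gaussian mean, seconds.
#' @param sigma Gaussian standard deviation, seconds; positive.
#' @param tau Mean of the exponential component, seconds; positive.
#' @return An object of class `"ex_gauss"`.
#' @export
ex_gauss <- function(mu = 0.3, sigma = 0.06, tau = 0.08) {
  stopifnot(is.numeric(mu), is.numeric(sigma), is.numeric(tau),
            length(mu) == 1L, length(sigma) == 1L, length(tau) == 1L)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "ex_gauss")
}

#' Virtual observer for response-signal SAT simulations
#'
#' Bundles an SAT curve, an ex-Gaussian response-time distribution and a task
#' specification into a simulated observer. On each trial the observer's RT is
#' an ex-Gaussian draw truncated to the response window `[soa, soa + window]`,
#' and the response is correct with probability `sat_pc(rt)` evaluated at the
#' realized RT (not at the SOA).
#'
#' @param sat A [sat_params()] object (or coercible list).
#' @param rtdist An [ex_gauss()] object; default matches the simulation study
#'   settings (mu = 0.3 s, sigma = 0.06 s, tau = 0.08 s).
#' @param task A [task_spec()] object; default 2AFC with a 0.2 s window.
#' @return An object of class `"virtual_observer"`.
#' @seealso [reference_observers()], [simulate_trials()]
#' @export
virtual_observer <- function(sat, rtdist = ex_gauss(), task = task_spec()) {
  structure(list(sat = as_sat_params(sat),
                 rtdist = rtdist,
                 task = as_task_spec(task)),
            class = "virtual_observer")
}

#' @export
print.virtual_observer <- function(x, ...) {
  cat("Virtual observer\n")
  cat(sprintf("  SAT:  lam = %.4g, gam = %.4g 1/s, delta = %.4g s\n",
              x$sat$lam, x$sat$gam, x$sat$delta))
  cat(sprintf("  RT:   ex-Gaussian mu = %.3g, sigma = %.3g, tau = %.3g s\n",
              x$rtdist$mu, x$rtdist$sigma, x$rtdist$tau))
  cat(sprintf("  Task: chance = %.3g, window = %.3g s\n",
              x$task$chance, x$task$window))
  invisible(x)
}

#' The four reference observers of the simulation study
#'
#' Four virtual observers spanning shallow and steep SAT curves, used
#' throughout the validation experiments: (0.470, 7.5, 0.28), (0.450, 5.0,
#' 0.22), (0.495, 22, 0.24) and (0.495, 20, 0.36) for (lam, gam 1/s, delta s),
#' all with the default ex-Gaussian RT distribution and 2AFC task.
#'
#' @param which Integer vector selecting observers 1-4; default all four.
#' @return A list of [virtual_observer()] objects.
#' @export
reference_observers <- function(which = 1:4) {
  tab <- list(c(0.470, 7.5, 0.28),
              c(0.450, 5.0, 0.22),
              c(0.495, 22,  0.24),
              c(0.495, 20,  0.36))
  stopifnot(all(which %in% 1:4))
  lapply(tab[which], function(p) virtual_observer(sat_params(p[1], p[2], p[3])))
}

#' Sample response times inside a response window
#'
#' Draws from the ex-Gaussian distribution truncated to
#' `[soa, soa + window]` by rejection: unconstrained draws are taken until one
#' lands in the window. If 1000 attempts fail (the window carries negligible
#' mass, e.g. very long SOAs), the draw falls back to a uniform sample on the
#' window; the number of fallback draws is attached as attribute
#' `"n_fallback"`.
#'
#' @param n Number of trials.
#' @param rtdist An [ex_gauss()] object.
#' @param soa Stimulus-onset asynchrony, seconds.
#' @param window Response window length, seconds.
#' @param max_tries Rejection attempts per trial before the uniform fallback.
#' @return Numeric vector of `n` response times in `[soa, soa + window]`.
#' @export
sample_rt <- function(n, rtdist = ex_gauss(), soa = 0, window = 0.2,
                      max_tries = 1000L) {
  stopifnot(n >= 0, window > 0, soa >= 0)
  out <- numeric(n)
  need <- seq_len(n)
  # accepted rejection draws are iid from the truncated distribution, so
  # candidates are generated in batches and assigned to pending trials;
  # the candidate budget is max_tries per requested trial
  budget <- as.double(n) * max_tries
  used <- 0
  while (length(need) > 0L && used < budget) {
    m <- min(length(need) * 64, budget - used)
    d <- stats::rnorm(m, rtdist$mu, rtdist$sigma) +
      stats::rexp(m, rate = 1 / rtdist$tau)
    used <- used + m
    d <- d[d >= soa & d <= soa + window]
    k <- min(length(d), length(need))
    if (k > 0L) {
      out[need[seq_len(k)]] <- d[seq_len(k)]
      need <- need[-seq_len(k)]
    }
  }
  nf <- length(need)
  if (nf > 0L) out[need] <- stats::runif(nf, soa, soa + window)
  structure(out, n_fallback = nf)
}

#' Simulate response-signal trials from a virtual observer
#'
#' Simulates `n` trials at each element of `soa` (recycled pairwise with `n`).
#' Each trial draws a window-truncated ex-Gaussian RT and labels the response
#' correct with probability `sat_pc(rt)`.
#'
#' @param object A [virtual_observer()].
#' @param soa SOA value(s), seconds.
#' @param n Trials per SOA value (scalar or vector matching `soa`).
#' @param block Optional block index value(s) recorded in the output; defaults
#'   to `seq_along(soa)`.
#' @return A data frame with columns `soa`, `rt`, `correct` (0/1) and `block`,
#'   one row per trial, with attribute `"n_fallback"` counting uniform RT
#'   fallbacks.
#' @examples
#' obs <- reference_observers(1)[[1]]
#' set.seed(1)
#' head(simulate_trials(obs, soa = 0.36, n = 5))
#' @export
simulate_trials <- function(object, soa, n = 16L, block = NULL) {
  stopifnot(inherits(object, "virtual_observer"),
            is.numeric(soa), all(soa >= 0), all(n >= 1))
  n <- rep_len(as.integer(n), length(soa))
  if (is.null(block)) block <- seq_along(soa)
  block <- rep_len(block, length(soa))
  nf <- 0L
  res <- vector("list", length(soa))
  for (i in seq_along(soa)) {
    rt <- sample_rt(n[i], object$rtdist, soa[i], object$task$window)
    nf <- nf + attr(rt, "n_fallback")
    pc <- sat_pc(as.numeric(rt), object$sat, object$task)
    correct <- as.integer(stats::runif(n[i]) < pc)
    res[[i]] <- data.frame(soa = soa[i], rt = as.numeric(rt),
                           correct = correct, block = block[i])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_fallback") <- nf
  out
}

#' Simulate a single block of trials at one SOA
#'
#' @param object A [virtual_observer()].
#' @param soa Block SOA, seconds.
#' @param n Trials in the block (>= 1).
#' @param block Block index recorded in the output.
#' @return A trial data frame as in [simulate_trials()].
#' @export
simulate_block <- function(object, soa, n = 16L, block = 1L) {
  stopifnot(length(soa) == 1L, n >= 1)
  simulate_trials(object, soa, n = n, block = block)
}

#' Simulate method for virtual observers
#'
#' `simulate()` draws `nsim` trials at each SOA in `soa`, mirroring
#' [simulate_trials()] with the standard `simulate()` seed handling.
#'
#' @param object A [virtual_observer()].
#' @param nsim Trials per SOA.
#' @param seed Optional integer seed.
#' @param soa SOA value(s), seconds.
#' @param ... Unused.
#' @return A trial data frame (`soa`, `rt`, `correct`, `block`).
#' @export
simulate.virtual_observer <- function(object, nsim = 1, seed = NULL,
                                      soa = 0.36, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_trials(object, soa = soa, n = nsim)
}
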