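#' @export
print.sat_fit <- function(x, digits = 4, ...) {
  cat(sprintf("SAT model fit (%s route, %d trials)\n",
              switch(x$method, bayes = "Bayesian grid",
                     trial = "trial-wise ML", mean = "SOA-averaged ML"),
              x$n_trials))
  print(round(x$coefficients, digits))
  if (!is.null(x$hwci))
    cat(sprintf("%.1f%% HWCI: lam %.4g, gam %.4g, delta %.4g\n",
                100 * x$level, x$hwci[1], x$hwci[2], x$hwci[3]))
  invisible(x)
}

#' @export
coef.sat_fit <- function(object, ...) object$coefficients

#' @export
logLik.sat_fit <- function(object, ...) {
  ll <- if (!is.null(object$logLik)) object$logLik else {
    # Bayesian route: log-likelihood at the posterior-mean parameters
    pq <- pc_q_vec(object$data$rt, object$coefficients, object$task$chance)
    sum(ifelse(object$data$correct == 1, log(pq$pc), log(pq$q)))
  }
  structure(ll, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' Summary of an SAT model fit
#'
#' @param object A [sat_fit()] object.
#' @param times Evaluation times (seconds) at which the fitted curve is
#'   tabulated.
#' @param ... Unused.
#' @return An object of class `"summary.sat_fit"`.
#' @export
summary.sat_fit <- function(object,
                            times = c(0.06, 0.09, 0.12, 0.24, 0.36, 0.48,
                                      0.6, 1.2), ...) {
  curve <- predict(object, times = times)
  structure(list(fit = object, times = times, curve = curve,
                 logLik = logLik(object)),
            class = "summary.sat_fit")
}

#' @export
print.summary.sat_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("log-likelihood: %.2f on %d trials\n",
              as.numeric(x$logLik), attr(x$logLik, "nobs")))
  cat("fitted probability correct:\n")
  tab <- data.frame(time = x$times, pc = round(x$curve, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict probability correct from a fitted SAT model
#'
#' @param object A [sat_fit()] object.
#' @param times Response times (seconds) at which to evaluate the curve;
#'   defaults to the observed RTs.
#' @param type `"plugin"` evaluates the curve at the point estimate;
#'   `"resample"` (Bayesian route only) averages curves reconstructed from
#'   `n_resamples` posterior draws and also returns the per-time HWCI.
#' @param n_resamples Posterior draws for `type = "resample"`.
#' @param ... Unused.
#' @return For `"plugin"`, a numeric vector of probability correct; for
#'   `"resample"`, the data frame of [reconstruct_sat()].
#' @export
predict.sat_fit <- function(object, times = NULL,
                            type = c("plugin", "resample"),
                            n_resamples = 1000L, ...) {
  type <- match.arg(type)
  if (is.null(times)) times <- object$data$rt
  if (type == "plugin") {
    pc_q_vec(times, object$coefficients, object$task$chance)$pc
  } else {
    if (is.null(object$posterior))
      stop("'resample' prediction requires a Bayesian fit", call. = FALSE)
    reconstruct_sat(object$posterior, times, n_resamples = n_resamples,
                    task = object$task)
  }
}

#' @export
fitted.sat_fit <- function(object, ...) {
  predict(object, times = object$data$rt)
}

#' @export
residuals.sat_fit <- function(object, ...) {
  object$data$correct - fitted(object)
}

#' Plot a fitted SAT function
#'
#' Draws the fitted probability-correct curve over response time, the chance
#' level, and the observed accuracies aggregated into RT bins (point area
#' proportional to trial count). For Bayesian fits the resampled
#' reconstruction band (per-time HWCI) is shaded.
#'
#' @param x A [sat_fit()] object.
#' @param n_bins Number of RT bins for the empirical accuracies.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sat_fit <- function(x, n_bins = 10L, ...) {
  rt_range <- range(x$data$rt)
  tt <- seq(max(0, rt_range[1] - 0.05), rt_range[2] + 0.05,
            length.out = 200L)
  pc <- predict(x, times = tt)
  graphics::plot(tt, pc, type = "n", ylim = c(0, 1),
                 xlab = "response time (s)", ylab = "probability correct",
                 ...)
  if (!is.null(x$posterior)) {
    band <- predict(x, times = tt, type = "resample", n_resamples = 500L)
    graphics::polygon(c(tt, rev(tt)), c(band$lower, rev(band$upper)),
                      border = NA,
                      col = grDevices::adjustcolor("steelblue", 0.25))
  }
  graphics::lines(tt, pc, lwd = 2, col = "steelblue")
  graphics::abline(h = x$task$chance, lty = 3)
  bins <- cut(x$data$rt, breaks = n_bins)
  acc <- tapply(x$data$correct, bins, mean)
  mid <- tapply(x$data$rt, bins, mean)
  cnt <- tapply(x$data$correct, bins, length)
  keep <- !is.na(acc)
  graphics::points(mid[keep], acc[keep],
                   cex = 0.5 + 1.5 * sqrt(cnt[keep] / max(cnt[keep])),
                   pch = 16, col = grDevices::adjustcolor("grey30", 0.7))
  invisible(x)
}

#' Simulate trials from a fitted SAT model
#'
#' Generates new response-signal trials from a virtual observer whose SAT
#' curve equals the fitted point estimate (RT distribution and task taken
#' from `rtdist` and the fit's task).
#'
#' @param object A [sat_fit()] object.
#' @param nsim Trials per SOA.
#' @param seed Optional integer seed.
#' @param soa SOA value(s), seconds; defaults to the distinct observed SOAs.
#' @param rtdist An [ex_gauss()] RT distribution.
#' @param ... Unused.
#' @return A trial data frame (`soa`, `rt`, `correct`, `block`).
#' @export
simulate.sat_fit <- function(object, nsim = 1, seed = NULL, soa = NULL,
                             rtdist = ex_gauss(), ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(soa)) soa <- sort(unique(object$data$soa))
  cf <- object$coefficients
  obs <- virtual_observer(sat_params(cf[["lam"]], cf[["gam"]], cf[["delta"]]),
                          rtdist = rtdist, task = object$task)
  simulate_trials(obs, soa = soa, n = nsim)
}
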