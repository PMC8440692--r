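#' Stimulus space of candidate SOAs
#'
#' @param soas Strictly increasing SOA values in seconds; default 49 equally
#'   spaced values on `[0, 1.2]`.
#' @return An object of class `"stimulus_space"`.
#' @export
stimulus_space <- function(soas = seq(0, 1.2, length.out = 49)) {
  if (is.unsorted(soas, strictly = TRUE))
    stop("SOA values must be strictly increasing", call. = FALSE)
  if (any(soas < 0)) stop("SOA values must be non-negative", call. = FALSE)
  structure(list(soas = soas), class = "stimulus_space")
}

#' Block design of the adaptive procedure
#'
#' @param n_trials Trials per block (>= 1), default 16.
#' @param window Response window length, seconds, default 0.2.
#' @return An object of class `"block_design"`.
#' @export
block_design <- function(n_trials = 16L, window = 0.2) {
  stopifnot(n_trials >= 1, window > 0)
  structure(list(n_trials = as.integer(n_trials), window = window),
            class = "block_design")
}

#' Expected response time of an SOA block
#'
#' For stimulus selection the realized RTs of a future block are summarized by
#' the midpoint of the response window: `soa + window / 2`.
#'
#' @param soa SOA value(s), seconds.
#' @param window Response window length, seconds.
#' @return Expected RT(s), seconds.
#' @examples
#' expected_rt(0.6, 0.2)  # 0.7
#' @export
expected_rt <- function(soa, window = 0.2) {
  stopifnot(all(soa >= 0), window > 0)
  soa + window / 2
}

#' Binomial block-outcome distribution
#'
#' Probability of observing `k = 0, ..., n` correct responses in an `n`-trial
#' block when each trial is correct with probability `pc`.
#'
#' @param pc Probability correct on a single trial, in `[0, 1]`.
#' @param n Trials in the block.
#' @return Numeric vector of length `n + 1` over `k = 0:n`; sums to 1.
#' @export
block_outcome_likelihood <- function(pc, n) {
  stopifnot(length(pc) == 1L, pc >= 0, pc <= 1, n >= 1)
  stats::dbinom(0:n, size = n, prob = pc)
}

# (n+1) x (n+1) upper-triangular map from raw moments of pc to the binomial
# pmf over k: p(k) = C(n,k) sum_j C(n-k, j) (-1)^j E[pc^(k+j)].
moment_transform <- function(n) {
  Tm <- matrix(0, n + 1L, n + 1L)
  for (k in 0:n)
    for (j in k:n)
      Tm[k + 1L, j + 1L] <- choose(n, k) * choose(n - k, j - k) *
        (-1)^(j - k)
  Tm
}

#' Precomputed tables for block-wise stimulus selection
#'
#' Caches every quantity of the expected-information-gain computation that
#' does not depend on the posterior: probability correct per grid cell at each
#' candidate SOA's expected RT, the per-cell conditional entropy of the
#' binomial block outcome, and the moment-to-pmf transform. Build once per
#' (grid, task, space, design) and reuse across blocks and replications.
#'
#' @param grid A [sat_grid()].
#' @param task A [task_spec()].
#' @param space A [stimulus_space()].
#' @param design A [block_design()].
#' @return An object of class `"selection_tables"`.
#' @export
selection_tables <- function(grid = sat_grid(), task = task_spec(),
                             space = stimulus_space(),
                             design = block_design()) {
  stopifnot(inherits(grid, "sat_grid"), inherits(space, "stimulus_space"),
            inherits(design, "block_design"))
  task <- as_task_spec(task)
  n <- design$n_trials
  k <- 0:n
  x <- expected_rt(space$soas, design$window)
  m <- prod(grid$dim)
  S <- length(x)
  PC <- matrix(0, m, S)
  Hc <- matrix(0, m, S)
  lch <- lchoose(n, k)
  for (s in seq_len(S)) {
    above <- x[s] > grid$del
    e <- exp(-grid$gam * pmax(x[s] - grid$del, 0))
    pc <- ifelse(above, task$chance + grid$lam * (1 - e), task$chance)
    q <- ifelse(above, (1 - task$chance - grid$lam) + grid$lam * e,
                1 - task$chance)
    PC[, s] <- pc
    # conditional entropy of Binomial(n, pc) per cell, guarding 0 log 0
    lB <- outer(log(pc), k) + outer(log(q), n - k) + rep(lch, each = m)
    B <- exp(lB)
    BlB <- B * lB
    BlB[B == 0] <- 0
    Hc[, s] <- -rowSums(BlB)
  }
  structure(list(grid = grid, task = task, space = space, design = design,
                 PC = PC, Hc = Hc, Tm = moment_transform(n)),
            class = "selection_tables")
}

#' Expected information gain of an SOA block
#'
#' Mutual information, in nats, between the number of correct responses in
#' the next `n`-trial block and the SAT parameters, under the current
#' posterior. All trial outcomes in the block are evaluated at the block's
#' expected RT (window midpoint). The gain is the entropy of the mixture
#' predictive outcome distribution minus the posterior-weighted conditional
#' outcome entropy; it is non-negative and bounded by the posterior entropy.
#'
#' @param post A `sat_posterior`.
#' @param tables A [selection_tables()] object built on the same grid.
#' @param soa Optional subset of SOAs (must belong to the stimulus space);
#'   default all candidates.
#' @return Named numeric vector of gains (nats), one per candidate SOA.
#' @export
expected_information_gain <- function(post, tables, soa = NULL) {
  stopifnot(inherits(post, "sat_posterior"),
            inherits(tables, "selection_tables"))
  if (length(post$w) != nrow(tables$PC))
    stop("posterior and selection tables use different grids", call. = FALSE)
  gain <- block_gain_cpp(post$w, tables$PC, tables$Hc,
                         tables$design$n_trials, tables$Tm)
  # the moment-to-pmf transform leaves ~1e-8 numerical noise at (near-)
  # degenerate posteriors; gains below 1e-7 nats are scientifically nil and
  # are floored to exact zero so that ties resolve deterministically
  gain[gain < 1e-7] <- 0
  names(gain) <- formatC(tables$space$soas, format = "g")
  if (!is.null(soa)) {
    i <- match(soa, tables$space$soas)
    if (anyNA(i)) stop("'soa' must belong to the stimulus space", call. = FALSE)
    gain <- gain[i]
  }
  gain
}

#' Select the next block's SOA
#'
#' The SOA with maximal expected information gain; ties (including the
#' all-zero gain of a degenerate posterior) break toward the smallest SOA.
#' Deterministic given the posterior.
#'
#' @inheritParams expected_information_gain
#' @return The selected SOA in seconds, with attributes `"index"` (position in
#'   the stimulus space) and `"gain"` (the full gain vector, nats).
#' @export
select_soa <- function(post, tables) {
  gain <- expected_information_gain(post, tables)
  best <- unname(which(gain >= max(gain) * (1 - 1e-9))[1L])
  structure(tables$space$soas[best], index = best, gain = gain)
}
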