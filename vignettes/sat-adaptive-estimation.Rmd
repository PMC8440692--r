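---
title: "Bayesian adaptive estimation of speed-accuracy tradeoff functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian adaptive estimation of speed-accuracy tradeoff functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satadapt)
```

## The model

In a response-signal experiment the participant may respond only within a
short window that opens at a stimulus-onset asynchrony (SOA) after stimulus
onset. Accuracy as a function of the realized response time $t$ follows a
conditional accuracy function: chance performance up to an intercept, then an
exponential rise to an asymptote,

$$\Psi(t) = \lambda\,\bigl(1 - e^{-\gamma (t - \delta)}\bigr)\quad (t > \delta),
\qquad \Psi(t) = 0 \quad (t \le \delta),$$

with total probability correct $p_c(t) = \mu + \Psi(t)$, where $\mu$ is the
guessing rate (0.5 for 2AFC). The three parameters have direct
interpretations: $\lambda$ (probability units, at most $1-\mu$) is the
asymptotic accuracy above chance, $\gamma$ (1/s) is how fast accuracy
grows once information becomes available, and $\delta$ (s) is the earliest
time at which performance rises above chance. `sat_psi()` and `sat_pc()`
implement exactly this pair; every simulation and every likelihood in the
package goes through `sat_pc()`, so chance levels other than 0.5 are
supported uniformly. The intercept itself evaluates to zero
($t = \delta$ belongs to the chance branch), which keeps the curve
right-continuous and the likelihood well defined for RTs at the boundary.

## Trial-based Bayesian estimation

The central idea is to use each trial's *binary* correctness at its
*realized* RT instead of averaging accuracy within SOA blocks. Given a trial
$(x, r)$ with RT $x$ and correctness $r \in \{0, 1\}$, the likelihood of a
parameter triple $\theta$ is $p_c(x;\theta)$ or $1 - p_c(x;\theta)$. A prior
on a rectangular grid — by default 21 $\lambda$ values on $[0.4, 0.5]$, 30
$\gamma$ values on $[1, 30]$, 25 $\delta$ values on $[0.02, 0.5]$, uniform —
is updated by pointwise multiplication and renormalization after every
trial (`posterior_update()`). Estimates are marginal posterior means;
precision is the half-width of the shortest credible interval (HWCI) at
68.2% coverage on each marginal. On the discrete grid the "shortest
interval" is the shortest contiguous run of grid points reaching the
coverage, ties broken toward the narrower window and then the smaller lower
bound; the uniform prior on the 21-point $\lambda$ axis has half-width
0.035 under this rule.

The estimated SAT *function* is reconstructed by resampling: 1000 parameter
triples drawn proportionally to posterior mass (inverse-CDF sampling), each
plugged into the model, and the curves averaged (`reconstruct_sat()`). The
per-time spread of the resampled curves (shortest 68.2% interval) is the
function-level precision. The resampling default of 1000 keeps the Monte
Carlo error of the reconstructed mean an order of magnitude below the
quantities of interest; `posterior_mean_curve()` provides the exact mixture
limit and is the oracle the tests compare against.

Numerical choices worth knowing about:

* Updates happen in linear space with renormalization after *every* trial,
  which is equivalent to accumulating log-likelihoods: no factor can
  underflow because single-trial likelihoods stay within
  $[\sim 10^{-17}, 1]$. The test suite verifies equality with a one-shot
  product formulation to $10^{-10}$.
* Incorrect-response likelihoods are computed as
  $(1 - \mu - \lambda) + \lambda e^{-\gamma(x-\delta)}$ rather than
  $1 - p_c$: at the grid corner $\lambda = 0.5$, $\gamma = 30$ and long RTs,
  $p_c$ rounds to exactly 1 in double precision while this form keeps a
  positive value.
* Posterior cells whose relative mass falls below $10^{-300}$ are flushed to
  exact zero. They are numerically irrelevant, and leaving them subnormal
  makes the selection kernel pay the hardware's denormal-arithmetic penalty
  (about an order of magnitude in wall time).

## Adaptive stimulus selection

The SOA for the next block is the candidate (49 equally spaced values on
$[0, 1.2]$ s) that maximizes the expected information gain about $\theta$,
i.e. the mutual information between the upcoming block's outcome and the
parameters. Because the block's RTs are unknown at selection time, all of
its trials are summarized by the expected RT, taken as the window midpoint
$x = \text{SOA} + w/2$; the number of correct responses $k$ out of $n$ block
trials then follows a binomial in $p_c(x;\theta)$, giving a
"multiple-step-ahead" search. The gain is

$$I(R;\Theta) = H\!\Bigl(\textstyle\sum_\theta p(\theta)\,p(k\mid x,\theta)\Bigr)
 - \sum_\theta p(\theta)\, H\bigl(p(k\mid x,\theta)\bigr),$$

with entropies in nats ($0\log 0 = 0$); the base only rescales the argmax.
With $n = 1$ this reduces to the classic one-trial-ahead information-gain
rule of adaptive psychophysics. Once a block is running, the posterior is
updated trial by trial on the *realized* (RT, correctness) pairs — the
binomial model is used only to predict the gain. We verified the
alternative (a single binomial update per block at the midpoint RT) and it
is markedly less accurate, because it discards the within-block RT
variation that identifies $\delta$ and $\gamma$.

Implementation: everything that does not depend on the posterior —
$p_c(x;\theta)$ per grid cell and candidate SOA, the conditional outcome
entropies, and a fixed linear map from the first $n$ raw moments of $p_c$
to the binomial mixture pmf — is precomputed once (`selection_tables()`).
Each selection then costs one pass over the grid per candidate (a C++
kernel), which is what makes 200-replication studies of 128 selections each
tractable. The moment-to-pmf map is an alternating sum and leaves
$\sim 10^{-8}$ nats of roundoff at nearly degenerate posteriors; gains below
$10^{-7}$ nats are floored to zero, and argmax ties resolve to the smallest
SOA, so selection is fully deterministic. The kernel is cross-checked
against direct `dbinom()` enumeration in the tests.

## The virtual observer

Simulated observers draw an RT from an ex-Gaussian distribution
($\mu_{RT} = 0.3$ s, $\sigma = 0.06$ s, $\tau = 0.08$ s — a typical
conflict-task RT profile) truncated to the response window
$[\text{SOA}, \text{SOA} + 0.2]$, and respond correctly with probability
$p_c(\text{RT})$ evaluated at the realized RT. Truncation is by rejection,
which preserves the conditional shape of the distribution; if 1000 draws
miss the window (long SOAs place essentially no ex-Gaussian mass there, e.g.
SOA = 1.2 s), the RT falls back to a uniform draw on the window and the
event is counted on the returned object. At such SOAs the SAT curve is
nearly flat, so the fallback has no visible effect on accuracy statistics.
The four reference observers (`reference_observers()`) span shallow to steep
curves: $(\lambda, \gamma, \delta)$ = (0.470, 7.5, 0.28), (0.450, 5.0,
0.22), (0.495, 22, 0.24), (0.495, 20, 0.36). Observer 1's $\gamma = 7.5$
deliberately sits off the $\gamma$ grid; no grid refinement is performed, to
keep estimates comparable with the reference setup.

What the simulator does *not* emulate: lapses and response bias, sequential
dependencies between trials, learning or fatigue (non-stationarity), and
RT distributions that shift with SOA. Passing tests therefore demonstrate
estimator correctness under the stated generative model, not robustness of
the method to real observers' misbehavior.

## The four procedures

`run_procedure()` implements four comparable designs sharing the trial
schema:

1. **MCS + averaged ML.** Eight fixed SOA levels (0.06-1.20 s) presented as
   randomized 16-trial blocks; at each checkpoint the accumulated trials are
   aggregated per SOA into a mean RT and correct count and the binomial
   likelihood is maximized. A long-block mode (one block per level) is
   available via `mcs_mode = "long"`.
2. **MCS + trial-wise ML.** Same data; the per-trial Bernoulli likelihood at
   each realized RT is maximized.
3. **MCS + Bayesian.** Same data; per-trial grid updates, online estimates.
4. **Adaptive + Bayesian.** Block SOAs chosen by expected information gain.

ML fits run `L-BFGS-B` inside the grid's axis ranges (bounds shared with the
Bayesian prior for comparability) from 8 Latin-hypercube starting points,
with the previous checkpoint's solution added as a warm start during
checkpointed runs; a least-squares objective is available as an alternative.
The optimizer uses a $10^{-6}$ finite-difference step — the default step is
too coarse for the shallow $\gamma$ ridge and leaves visible bias. Fits with
fewer than three distinct SOAs (or RTs) are flagged unidentifiable and
recorded as missing rather than aborting the run. Checkpoints default to
powers of two up to the total plus the 100-trial point.

## Evaluation metrics

Accuracy of a parameter is the mean absolute error over replications.
For the function, evaluated at the eight standard time points, two
"average absolute bias" readings exist: the replication-wise mean absolute
error, and a variant in which signed errors are summed across replications
before taking the absolute value (so opposite-signed errors cancel). The
reference trajectories the test suite compares against are reproduced by
the former,
which `evaluate_runs()` reports as `fbias_mae`; the cancelling form is kept
alongside as `fbias` (it is never larger, by the triangle inequality).
Precision is the pooled SD of curve values around their per-time
replication mean, and — for Bayesian fits — the mean function HWCI.

The trials-to-precision comparison finds where the SD trajectory crosses
0.020: since Bayesian trajectories start near zero (all replications share
the prior), rise, and fall, the crossing is searched *after* the
trajectory's peak and linearly interpolated between checkpoints. For the
monotone trajectories of the ML procedures this is the plain first
crossing. A caveat worth stating: near the threshold some SD trajectories
plateau within a few thousandths of 0.020, and there the crossing point is
an ill-conditioned summary — small differences in dispersion move it by
hundreds of trials. The bias and HWCI trajectories are the stable summaries;
the crossing is reported for comparability.

## Study sizes

The replicated studies in the test suite and the acceptance script use 200
replications per condition, full 2048-trial runs for the main adaptive
study, and shortened horizons where only early checkpoints are read (112
trials for the 100-trial claim, 256 for the observer-4 precision study,
1024 for the conventional-procedure precision study). Two hundred
replications put the standard error of the bias metrics near 5% of their
values, which is the resolution the comparisons need.

## Limitations

* The $\lambda$ prior range $[0.4, 0.5]$ encodes near-perfect asymptotic
  2AFC performance; observers with lower asymptotes need a wider grid
  (`sat_grid()` accepts arbitrary axes, and the ML bounds follow the grid).
* The midpoint expected-RT summary used for selection is biased at short
  SOAs, where the truncated RT distribution leans toward the window's upper
  edge; a better RT summary would sharpen selection slightly.
* Grid-based inference costs memory and time proportional to the number of
  cells; the default 15,750-cell grid is comfortable, but much finer grids
  would call for sparsification.
* One-block lookahead is myopic; deeper planning is out of scope.
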