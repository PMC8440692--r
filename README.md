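# satadapt

Bayesian adaptive estimation of speed–accuracy tradeoff (SAT) functions
measured with the response-signal paradigm.

## The problem

Response time and accuracy trade off against each other, so neither alone
characterizes cognitive performance. Response-signal experiments map the
whole tradeoff by forcing responses into a short window placed at a chosen
stimulus-onset asynchrony (SOA) and measuring accuracy as a function of
response time. The standard analysis — many long blocks per SOA level, then
a curve fit to per-block mean RT and accuracy — needs thousands of trials,
which rules the paradigm out for clinical and developmental populations.

`satadapt` implements two remedies and the machinery to evaluate them:

* **Trial-based Bayesian estimation.** Each trial's *binary* correctness at
  its *realized* RT updates a grid posterior over the SAT parameters, so
  every trial is informative and no averaging is needed.
* **Adaptive stimulus selection.** Each block's SOA is chosen to maximize
  the expected information gain about the parameters, using a binomial
  model of the upcoming block's correct count ("multiple-step-ahead"
  search).

The SAT curve is the conditional accuracy function

    pc(t) = chance + lambda * (1 - exp(-gamma * (t - delta)))   for t > delta
    pc(t) = chance                                              otherwise

with asymptote `lambda` (above-chance probability), rate `gamma` (1/s) and
intercept `delta` (s).

The package provides: the model (`sat_psi()`, `sat_pc()`), ex-Gaussian
virtual observers (`virtual_observer()`, `simulate_trials()`), the central
fitting interface (`sat_fit()`, methods `"bayes"`, `"trial"`, `"mean"`),
the grid engine (`posterior_update()`, `posterior_hwci()`,
`reconstruct_sat()`), adaptive selection (`selection_tables()`,
`select_soa()`), the four estimation procedures of the validation study
(`run_procedure()`, `run_study()`, `run_experiment()`), and
accuracy/precision evaluation (`evaluate_runs()`, `trials_to_precision()`).
A thin command-line front end ships in `inst/cli/satadapt.R`.

## Worked example

Simulate a response-signal session from a reference observer
(`lambda = 0.47`, `gamma = 7.5`, `delta = 0.28`), fit the SAT function
Bayesianly, and ask the adaptive rule where to test next:

```r
library(satadapt)
obs <- reference_observers(1)[[1]]
set.seed(42)
dat <- simulate_trials(obs, soa = rep(c(0.06, 0.12, 0.24, 0.36, 0.6, 1.2), 8),
                       n = 16)
fit <- sat_fit(dat, method = "bayes")
fit
#> SAT model fit (Bayesian grid route, 768 trials)
#>    lam    gam  delta
#> 0.4882 9.1221 0.2993
#> 68.2% HWCI: lam 0.005, gam 1.5, delta 0.01

predict(fit, times = c(0.3, 0.5, 1.0))
#> [1] 0.5031941 0.9099605 0.9873793

tab <- selection_tables()
select_soa(fit$posterior, tab)[1]
#> [1] 0.225
```

After 768 trials the posterior mean sits near the generating parameters
(the half-width credible intervals quantify the remaining uncertainty:
0.005 on `lambda`, 1.5 on `gamma`, 0.01 on `delta`), the fitted curve gives
the probability correct at any response time, and the information-gain rule
proposes the next block at SOA 0.225 s — near the curve's rise, where a
block is most informative about `delta` and `gamma`.

`plot(fit)` draws the fitted curve with its credible band over binned
observed accuracies; `run_procedure()` / `run_study()` scale this up to the
full simulated experiments.

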