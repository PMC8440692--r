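test_that("uniform prior has equal, normalized mass", {
  p <- sat_prior(sat_grid())
  expect_length(p$w, 21 * 30 * 25)
  expect_true(all(p$w == 1 / 15750))
  expect_equal(sum(p$w), 1, tolerance = 1e-12)
  p2 <- sat_prior(sat_grid(c(0.4, 0.5), c(1, 2), c(0.1, 0.2)))
  expect_true(all(p2$w == 1 / 8))
})

test_that("trial likelihood is flat below every intercept and complements sum to 1", {
  g <- sat_grid()
  l1 <- trial_likelihood(g, rt = 0.01, correct = 1)
  l0 <- trial_likelihood(g, rt = 0.01, correct = 0)
  expect_true(all(l1 == 0.5) && all(l0 == 0.5))
  l1 <- trial_likelihood(g, rt = 0.7, correct = 1)
  l0 <- trial_likelihood(g, rt = 0.7, correct = 0)
  expect_equal(l1 + l0, rep(1, length(l1)), tolerance = 1e-12)
  expect_true(all(l1 > 0 & l1 < 1))
  # at a cell holding observer 1's parameters the likelihood equals pc
  g2 <- sat_grid(lam = c(0.4, 0.47), gam = c(5, 7.5), delta = c(0.1, 0.28))
  i <- which(g2$lam == 0.47 & g2$gam == 7.5 & g2$del == 0.28)
  expect_equal(trial_likelihood(g2, 0.7, 1)[i], 0.9498595, tolerance = 1e-6)
})

test_that("updates match the brute-force product oracle on a tiny grid", {
  g <- tiny_grid()
  set.seed(11)
  trials <- data.frame(rt = runif(10, 0.05, 1.0),
                       correct = rbinom(10, 1, 0.7))
  post <- posterior_update(sat_prior(g), trials)
  expect_equal(post$w, brute_posterior(g, trials), tolerance = 1e-10)
  expect_equal(sum(post$w), 1, tolerance = 1e-12)
})

test_that("sequential updates equal a single joint update and are order invariant", {
  g <- sat_grid()
  set.seed(12)
  trials <- data.frame(rt = runif(40, 0.1, 1.2),
                       correct = rbinom(40, 1, 0.8))
  seq_post <- sat_prior(g)
  for (i in seq_len(nrow(trials)))
    seq_post <- posterior_update(seq_post, trials[i, ])
  joint <- posterior_update(sat_prior(g), trials)
  expect_equal(seq_post$w, joint$w, tolerance = 1e-10)
  perm <- posterior_update(sat_prior(g), trials[sample(40), ])
  expect_equal(perm$w, joint$w, tolerance = 1e-10)
  # uninformative trial leaves the posterior unchanged
  same <- posterior_update(joint, data.frame(rt = 0.01, correct = 1))
  expect_equal(same$w, joint$w, tolerance = 1e-12)
})

test_that("a single update is prior times likelihood, renormalized", {
  g <- sat_grid(lam = c(0.41, 0.45), gam = c(5), delta = c(0.1))
  rt <- 0.6
  l <- trial_likelihood(g, rt, 1)
  post <- posterior_update(sat_prior(g), data.frame(rt = rt, correct = 1))
  expect_equal(post$w, l / sum(l), tolerance = 1e-12)
})

test_that("marginals collapse the grid correctly", {
  g <- sat_grid(c(0.42, 0.48), c(3, 9), c(0.1, 0.3))
  set.seed(13)
  post <- posterior_update(sat_prior(g),
                           data.frame(rt = runif(6, 0.1, 1),
                                      correct = rbinom(6, 1, 0.8)))
  w <- array(post$w, dim = c(2, 2, 2))
  m <- posterior_marginal(post, "lam")
  expect_equal(m$mass, apply(w, 1, sum), tolerance = 1e-12)
  m <- posterior_marginal(post, "gam")
  expect_equal(m$mass, apply(w, 2, sum), tolerance = 1e-12)
  m <- posterior_marginal(post, "delta")
  expect_equal(m$mass, apply(w, 3, sum), tolerance = 1e-12)
  for (p in c("lam", "gam", "delta"))
    expect_equal(sum(posterior_marginal(post, p)$mass), 1, tolerance = 1e-12)
})

test_that("posterior mean of the uniform prior sits at the grid midpoints", {
  est <- posterior_mean(sat_prior(sat_grid()))
  expect_equal(est$lam, 0.45, tolerance = 1e-12)
  expect_equal(est$gam, 15.5, tolerance = 1e-12)
  expect_equal(est$delta, 0.26, tolerance = 1e-12)
  # degenerate posterior at observer 3's (on-grid) parameters
  pm <- point_mass_posterior(sat_grid(), 0.495, 22, 0.24)
  est <- posterior_mean(pm)
  expect_equal(c(est$lam, est$gam, est$delta), c(0.495, 22, 0.24))
})

test_that("shortest credible intervals follow the discrete rule", {
  lam_axis <- seq(0.4, 0.5, length.out = 21)
  # uniform 21-point marginal: 15 points cover 0.682, half-width 0.035
  ci <- hwci_mass(rep(1 / 21, 21), lam_axis)
  expect_equal(ci$half_width, 0.035, tolerance = 1e-12)
  # ties break toward the smaller lower bound
  expect_equal(ci$lower, 0.4)
  # point mass
  m <- rep(0, 21); m[7] <- 1
  expect_equal(hwci_mass(m, lam_axis)$half_width, 0)
  # full coverage
  expect_equal(hwci_mass(rep(1 / 21, 21), lam_axis, level = 1)$half_width,
               0.05, tolerance = 1e-12)
  # asymmetric mass: window must cover the heavy center
  m <- c(0.1, 0.8, 0.1)
  ci <- hwci_mass(m, c(1, 2, 3), level = 0.9)
  expect_equal(c(ci$lower, ci$upper), c(1, 2))
  expect_error(hwci_mass(c(0.5, 0.5), 1, level = 0.5))
})

test_that("posterior HWCI of the uniform prior matches the analytic value", {
  p <- sat_prior(sat_grid())
  expect_equal(posterior_hwci(p, "lam")$half_width, 0.035, tolerance = 1e-12)
})

test_that("function reconstruction averages resampled curves", {
  g <- sat_grid()
  task <- task_spec()
  pm <- point_mass_posterior(g, 0.495, 22, 0.24)
  set.seed(14)
  rec <- reconstruct_sat(pm, times8, n_resamples = 50, task = task)
  expect_equal(rec$pc, sat_pc(times8, sat_params(0.495, 22, 0.24), task),
               tolerance = 1e-12)
  expect_true(all(rec$hwci == 0))
  # resampled mean converges to the exact posterior mixture
  set.seed(15)
  post <- posterior_update(sat_prior(g),
                           data.frame(rt = runif(50, 0.1, 1.2),
                                      correct = rbinom(50, 1, 0.8)))
  exact <- posterior_mean_curve(post, times8, task)
  rec <- reconstruct_sat(post, times8, n_resamples = 8000, task = task)
  expect_equal(rec$pc, exact, tolerance = 0.01)
  expect_true(all(rec$pc >= 0.5 & rec$pc <= 1))
  expect_true(all(rec$lower <= rec$upper))
  expect_equal(rec$hwci, (rec$upper - rec$lower) / 2, tolerance = 1e-12)
})

test_that("posterior concentrates on on-grid truth as trials accumulate", {
  obs <- reference_observers(3)[[1]]  # fully on-grid parameters
  set.seed(16)
  d <- simulate_trials(obs, soa = rep(times8, 32), n = 8)  # 2048 trials
  post <- posterior_update(sat_prior(sat_grid()), d)
  est <- posterior_mean(post)
  # tolerance: 3x the scale of the reported final biases
  expect_lt(abs(est$lam - 0.495), 0.021)
  expect_lt(abs(est$gam - 22), 4)
  expect_lt(abs(est$delta - 0.24), 0.024)
  # credible intervals shrink with data
  early <- posterior_update(sat_prior(sat_grid()), d[1:128, ])
  for (p in c("lam", "gam", "delta"))
    expect_lt(posterior_hwci(post, p)$half_width,
              posterior_hwci(early, p)$half_width + 1e-9)
  expect_equal(sum(post$w), 1, tolerance = 1e-12)
})

test_that("posterior snapshots round-trip through JSON", {
  set.seed(17)
  post <- posterior_update(sat_prior(tiny_grid()),
                           data.frame(rt = runif(5, 0.1, 1),
                                      correct = rbinom(5, 1, 0.8)))
  f <- tempfile(fileext = ".json")
  write_posterior(post, f)
  back <- read_posterior(f)
  expect_equal(back$w, post$w, tolerance = 1e-12)
  expect_equal(back$grid$lam_axis, post$grid$lam_axis)
  expect_equal(back$n_trials, post$n_trials)
  unlink(f)
})

test_that("impossible update requests are rejected", {
  p <- sat_prior(tiny_grid())
  expect_error(posterior_update(p, data.frame(rt = -1, correct = 1)))
  expect_error(posterior_update(p, data.frame(rt = 0.5, correct = 2)))
})
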