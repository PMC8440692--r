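test_that("expected RT is the window midpoint", {
  expect_equal(expected_rt(0.6, 0.2), 0.7)
  expect_equal(expected_rt(0, 0.2), 0.1)
  expect_equal(expected_rt(1.2, 0.2), 1.3)
  expect_equal(expected_rt(c(0, 0.6), 0.1), c(0.05, 0.65))
})

test_that("block outcome distribution is the binomial pmf", {
  expect_equal(block_outcome_likelihood(0.5, 2), c(0.25, 0.5, 0.25))
  l <- block_outcome_likelihood(1, 16)
  expect_equal(l[17], 1)
  expect_equal(sum(l), 1)
  expect_equal(block_outcome_likelihood(0.95, 16)[17], 0.95^16,
               tolerance = 1e-12)
  expect_equal(block_outcome_likelihood(0.95, 16)[17], 0.4401,
               tolerance = 1e-4)
  expect_error(block_outcome_likelihood(1.2, 4))
})

test_that("expected information gain matches dbinom enumeration", {
  g <- tiny_grid()
  task <- task_spec()
  space <- stimulus_space(seq(0, 1.2, length.out = 13))
  for (n in c(1, 4, 16)) {
    tab <- selection_tables(g, task, space, block_design(n))
    set.seed(21)
    post <- posterior_update(sat_prior(g),
                             data.frame(rt = runif(8, 0.1, 1.2),
                                        correct = rbinom(8, 1, 0.8)))
    gain <- unname(expected_information_gain(post, tab))
    oracle <- brute_gain(post, task, space$soas, n)
    big <- oracle > 1e-6
    expect_lt(max(abs(gain[big] - oracle[big])), 1e-7)
    expect_lt(max(gain[!big]), 2e-6)
  }
})

test_that("gain on the default grid matches the oracle at full block length", {
  tab <- selection_tables()
  set.seed(22)
  post <- posterior_update(sat_prior(sat_grid()),
                           data.frame(rt = runif(64, 0.1, 1.3),
                                      correct = rbinom(64, 1, 0.85)))
  gain <- unname(expected_information_gain(post, tab))[idx <- c(1, 9, 25, 41, 49)]
  oracle <- brute_gain(post, task_spec(), tab$space$soas[idx], 16)
  big <- oracle > 1e-6
  expect_lt(max(abs(gain[big] - oracle[big])), 1e-7)
})

test_that("gain is non-negative and bounded by the posterior entropy", {
  tab <- selection_tables()
  post <- sat_prior(sat_grid())
  set.seed(23)
  for (i in 1:3) {
    gain <- expected_information_gain(post, tab)
    expect_true(all(gain >= 0))
    expect_true(all(gain <= posterior_entropy(post) + 1e-9))
    post <- posterior_update(post,
                             data.frame(rt = runif(32, 0.1, 1.3),
                                        correct = rbinom(32, 1, 0.8)))
  }
})

test_that("a resolved posterior has nothing to learn and ties break low", {
  g <- sat_grid()
  tab <- selection_tables(g)
  pm <- point_mass_posterior(g, 0.495, 22, 0.24)
  gain <- expected_information_gain(pm, tab)
  expect_true(all(gain == 0))
  soa <- select_soa(pm, tab)
  expect_equal(as.numeric(soa), 0)  # smallest SOA on ties
  expect_equal(attr(soa, "index"), 1L)
})

test_that("selection is deterministic given the posterior", {
  tab <- selection_tables()
  set.seed(24)
  post <- posterior_update(sat_prior(sat_grid()),
                           data.frame(rt = runif(16, 0.1, 1.3),
                                      correct = rbinom(16, 1, 0.8)))
  s1 <- select_soa(post, tab)
  s2 <- select_soa(post, tab)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_true(as.numeric(s1) %in% tab$space$soas)
})

test_that("an uninformative stimulus yields (near) zero gain", {
  # expected RT below every grid intercept: all cells predict pure chance
  g <- sat_grid(delta = seq(0.2, 0.5, length.out = 10))
  space <- stimulus_space(c(0, 0.05, 0.5))
  tab <- selection_tables(g, task_spec(), space, block_design(16))
  post <- sat_prior(g)
  gain <- expected_information_gain(post, tab)
  expect_lt(gain[1], 1e-12)   # x = 0.1 < min delta = 0.2
  expect_lt(gain[2], 1e-12)   # x = 0.15 < 0.2
  expect_gt(gain[3], 0.01)    # x = 0.6 discriminates
})

test_that("updating on selected blocks reduces posterior entropy on average", {
  g <- tiny_grid()
  obs <- virtual_observer(sat_params(0.46, 10, 0.25))
  tab <- selection_tables(g, obs$task, stimulus_space(), block_design(4))
  set.seed(25)
  post <- sat_prior(g)
  gains <- numeric(60)
  for (b in 1:60) {
    soa <- select_soa(post, tab)
    h0 <- posterior_entropy(post)
    blk <- simulate_block(obs, as.numeric(soa), n = 4)
    post <- posterior_update(post, blk)
    gains[b] <- h0 - posterior_entropy(post)
  }
  expect_gt(mean(gains), 0)
})

test_that("selection tables validate their inputs", {
  expect_error(stimulus_space(c(0.2, 0.1)), "increasing")
  expect_error(block_design(0), "n_trials")
  tab <- selection_tables(tiny_grid())
  expect_error(expected_information_gain(sat_prior(sat_grid()), tab),
               "different grids")
  expect_error(expected_information_gain(sat_prior(tiny_grid()), tab,
                                         soa = 0.123), "stimulus space")
})
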