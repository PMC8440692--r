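# Shared fixtures and independent oracles used across test files.

times8 <- c(0.06, 0.09, 0.12, 0.24, 0.36, 0.48, 0.60, 1.20)

obs1_params <- sat_params(0.470, 7.5, 0.28)
obs3_params <- sat_params(0.495, 22, 0.24)

# a small grid for brute-force comparisons
tiny_grid <- function() {
  sat_grid(lam = c(0.42, 0.46, 0.5), gam = c(4, 10, 20),
           delta = c(0.1, 0.25, 0.4))
}

# brute-force posterior: explicit prior x likelihood products, normalized once
brute_posterior <- function(grid, trials, task = task_spec()) {
  m <- prod(grid$dim)
  w <- rep(1 / m, m)
  lik <- rep(1, m)
  for (i in seq_len(nrow(trials))) {
    t <- trials$rt[i]
    psi <- ifelse(t > grid$del,
                  grid$lam * (1 - exp(-grid$gam * (t - grid$del))), 0)
    pc <- task$chance + psi
    lik <- lik * if (trials$correct[i] == 1) pc else (1 - pc)
  }
  w <- w * lik
  w / sum(w)
}

# brute-force expected information gain via dbinom enumeration (nats)
brute_gain <- function(post, task, soas, n, window = task$window) {
  g <- post$grid
  vapply(soas, function(soa) {
    x <- soa + window / 2
    psi <- ifelse(x > g$del, g$lam * (1 - exp(-g$gam * (x - g$del))), 0)
    pc <- task$chance + psi
    B <- t(vapply(pc, function(p) dbinom(0:n, n, p), numeric(n + 1)))
    Pk <- as.vector(crossprod(B, post$w))
    hmarg <- -sum(Pk[Pk > 0] * log(Pk[Pk > 0]))
    hcond <- -rowSums(B * ifelse(B > 0, log(B), 0))
    hmarg - sum(post$w * hcond)
  }, numeric(1))
}

# a point-mass posterior at the grid cell nearest the given parameters
point_mass_posterior <- function(grid, lam, gam, delta) {
  post <- sat_prior(grid)
  i <- which.min((grid$lam - lam)^2 + (grid$gam - gam)^2 +
                   (grid$del - delta)^2)
  post$w <- rep(0, length(post$w))
  post$w[i] <- 1
  post
}
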