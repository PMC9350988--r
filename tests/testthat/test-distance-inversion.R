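# Non-negative Tikhonov inversion, lambda selection, validation bands,
# reliability ranges.

test_that("unconstrained 5x5 problem matches the closed-form solution", {
  # construct a case whose regularised unconstrained optimum is positive
  set.seed(4)
  K <- diag(5) + matrix(runif(25, 0, 0.1), 5)
  p_true <- c(2, 3, 4, 3, 2)
  S <- as.vector(K %*% p_true) * 0.2          # kernel already includes dr here
  tr <- dipolar_trace(seq(0, 0.4, by = 0.1), S / S[1])
  kern <- structure(list(matrix = K, t_grid = tr$t,
                         r_grid = seq(2, 2.4, by = 0.1) * 2,
                         dipolar_constant = 52.04), class = "dipolar_kernel")
  # replicate the internal scaling: A = K * dr
  dr <- mean(diff(kern$r_grid))
  A <- K * dr
  L <- ridmekd:::second_difference(5)
  lambda <- 0.05
  closed <- solve(crossprod(A) + lambda^2 * crossprod(L), crossprod(A, tr$v_real))
  expect_true(all(closed > 0))                # premise of the comparison
  p_hat <- tikhonov_invert(tr, kern, lambda)
  expect_equal(p_hat$p, as.numeric(closed) / trapz(kern$r_grid, as.numeric(closed)),
               tolerance = 1e-8)
})

test_that("a noise-free Gaussian is recovered at small lambda", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.05)
  kern <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  S <- simulate_form_factor(g, 1, kern)        # delta = 1: pure dipolar signal
  p <- tikhonov_invert(S, kern, 1e-3)
  w <- ridmekd:::trapz_weights(rg)
  mu <- sum(w * rg * p$p)
  sdv <- sqrt(sum(w * (rg - mu)^2 * p$p))
  expect_lt(abs(mu - 2.5), 0.05)
  expect_lt(abs(sdv - 0.15), 0.3 * 0.15)
  expect_true(all(p$p >= 0))
  expect_equal(trapz(rg, p$p), 1, tolerance = 1e-9)
})

test_that("the regulariser dominates as lambda grows", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.05)
  kern <- dipolar_kernel(tg, rg)
  S <- simulate_form_factor(gaussian_distribution(2.5, 0.15, rg), 1, kern)
  sems <- vapply(c(0.1, 1, 10, 100),
                 function(l) attr(tikhonov_invert(S, kern, l), "seminorm"),
                 numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_error(tikhonov_invert(S, kern, -1), "positive")
})

test_that("lambda selection: noise-free limit, oracle proximity, scale equivariance", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.05)
  kern <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  S <- simulate_form_factor(g, 1, kern)
  grid <- 10^seq(-3, 3, by = 0.25)

  # noise-free: residual term dominates; selection falls to the bottom decade
  expect_warning(l0 <- select_lambda(S, kern, grid), "degenerate L-curve")
  expect_lte(l0, min(grid) * 10)

  # noisy: within one decade of the true-error-minimising lambda
  Sn <- add_noise(S, 0.01, seed = 7)
  lsel <- select_lambda(Sn, kern, grid)
  err <- vapply(grid, function(l)
    sqrt(sum((tikhonov_invert(Sn, kern, l)$p - g$p)^2)), numeric(1))
  loracle <- grid[which.min(err)]
  expect_lte(abs(log10(lsel) - log10(loracle)), 1)

  # scaling signal (hence noise) by 10 must not move the corner
  S10 <- Sn; S10$v_real <- 10 * S10$v_real
  expect_equal(select_lambda(S10, kern, grid), lsel)

  expect_error(select_lambda(S, kern, c(1, 10)), "4 decades")
})

test_that("validation bands: degenerate limit, stability, invariants", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.1)
  kern <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  S <- add_noise(simulate_form_factor(g, 1, kern), 0.01, seed = 5)

  # zero noise fraction: zero-width bands equal to the single inversion
  v0 <- validate_distribution(S, kern, 0.1, n_trials = 20,
                              noise_fraction = 0, seed = 1, noise_rms = 0.01)
  single <- tikhonov_invert(S, kern, 0.1)
  expect_equal(v0$dist$p, single$p, tolerance = 1e-12)
  expect_equal(v0$ci_lower, v0$ci_upper, tolerance = 1e-12)

  v1 <- validate_distribution(S, kern, 0.1, n_trials = 50, seed = 2,
                              noise_rms = 0.01)
  v2 <- validate_distribution(S, kern, 0.1, n_trials = 100, seed = 2,
                              noise_rms = 0.01)
  expect_true(all(v1$ci_lower <= v1$dist$p + 1e-12))
  expect_true(all(v1$ci_upper >= v1$dist$p - 1e-12))
  expect_true(all(v1$dist$p >= 0))
  # doubling the trials moves the mean band width by < 20%
  bw1 <- mean(v1$ci_upper - v1$ci_lower)
  bw2 <- mean(v2$ci_upper - v2$ci_lower)
  expect_lt(abs(bw2 - bw1) / bw1, 0.2)

  expect_error(validate_distribution(S, kern, 0.1, n_trials = 5, noise_rms = 0.01),
               ">= 20")
  expect_error(validate_distribution(S, kern, 0.1, n_trials = 50), "noise_rms")
})

test_that("reliability ranges follow the cube-root trace-length law", {
  rg <- seq(1.5, 12, by = 0.5)
  lab2 <- reliability_ranges(2, rg)
  # at t_max = 2 us the configured constants apply exactly
  expect_identical(as.character(lab2[rg <= 5]), rep("shape", sum(rg <= 5)))
  expect_identical(as.character(lab2[rg > 5 & rg <= 6]),
                   rep("mean_width", sum(rg > 5 & rg <= 6)))
  expect_identical(as.character(lab2[rg > 6 & rg <= 6.5]),
                   rep("mean", sum(rg > 6 & rg <= 6.5)))
  expect_identical(as.character(lab2[rg > 6.5]), rep("none", sum(rg > 6.5)))
  expect_true(!is.unsorted(lab2))             # monotone in r

  # quadrupling t_max scales every threshold by 4^(1/3)
  sc <- 4^(1 / 3)
  lab8 <- reliability_ranges(8, rg)
  expect_identical(as.character(lab8[rg <= 5 * sc]),
                   rep("shape", sum(rg <= 5 * sc)))
  expect_identical(as.character(lab8[rg > 6.5 * sc]),
                   rep("none", sum(rg > 6.5 * sc)))
  expect_error(reliability_ranges(0, rg), "positive")
})

test_that("point-estimate residuals are white at the oracle lambda", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.1)
  kern <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  S0 <- simulate_form_factor(g, 1, kern)
  A <- kern$matrix * mean(diff(rg))
  grid <- 10^seq(-2, 1, by = 0.25)
  white <- vapply(1:20, function(s) {
    Sn <- add_noise(S0, 0.01, seed = 500 + s)
    err <- vapply(grid, function(l)
      sqrt(sum((tikhonov_invert(Sn, kern, l)$p - g$p)^2)), numeric(1))
    p <- tikhonov_invert(Sn, kern, grid[which.min(err)])$p
    res <- Sn$v_real - as.vector(A %*% p)
    stats::Box.test(res, lag = 10, type = "Ljung-Box")$p.value > 0.01
  }, logical(1))
  expect_gte(mean(white), 0.8)
})

test_that("recovered mean distance is unbiased over seeds at SNR 20", {
  tg <- default_t_grid()
  rg <- default_r_grid(dr = 0.1)
  kern <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  S0 <- simulate_form_factor(g, 1, kern)
  w <- ridmekd:::trapz_weights(rg)
  mus <- vapply(1:50, function(s) {
    Sn <- add_noise(S0, 0.05, seed = 700 + s)   # SNR = delta/sigma = 20
    p <- tikhonov_invert(Sn, kern, 0.1)$p
    sum(w * rg * p)
  }, numeric(1))
  expect_lt(abs(mean(mus) - 2.5), 0.05)
})
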