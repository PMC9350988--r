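# Raw trace -> form factor -> modulation depth, noise, sensitivity.

test_that("phase correction recovers constructed rotations", {
  tg <- tiny_t()
  base <- exp(-0.2 * tg)

  # purely real input is unchanged
  tr <- dipolar_trace(tg, base, v_imag = rep(0, length(tg)))
  expect_equal(phase_correct(tr)$v_real, base)

  # +30 degree rotation recovered within 0.1 degree
  th <- 30 * pi / 180
  rot <- dipolar_trace(tg, base * cos(th), v_imag = base * sin(th))
  out <- phase_correct(rot)
  expect_equal(out$meta$phase_deg, 30, tolerance = 0.1)
  expect_lt(sqrt(mean(out$v_imag^2)), 1e-12)

  expect_error(phase_correct(dipolar_trace(tg, 0 * tg, v_imag = 0 * tg)),
               "degenerate")
})

test_that("phasing a noisy complex trace matches the grid-search oracle", {
  tg <- tiny_t()
  base <- exp(-0.2 * tg)
  th <- 52 * pi / 180
  sig <- 0.01
  set.seed(11)
  vr <- base * cos(th) + rnorm(length(tg), 0, sig)
  vi <- base * sin(th) + rnorm(length(tg), 0, sig)
  out <- phase_correct(dipolar_trace(tg, vr, v_imag = vi))
  tail_rms <- function(x) sqrt(mean(utils::tail(x, ceiling(length(x) / 2))^2))
  expect_lt(tail_rms(out$v_imag), 1.2 * sig)

  # oracle: exhaustive 0.01-degree grid over the tail objective
  grid <- seq(0, 180, by = 0.01) * pi / 180
  n <- length(tg); idx <- (n - ceiling(n / 2) + 1):n
  obj <- vapply(grid, function(a)
    sqrt(mean((vi[idx] * cos(a) - vr[idx] * sin(a))^2)), numeric(1))
  expect_lte(tail_rms(out$v_imag), min(obj) * (1 + 1e-6))
})

test_that("zero-time correction and normalisation behave", {
  tg <- tiny_t()
  v <- exp(-0.3 * tg)

  # already maximal at the first point: pure rescale
  tr <- dipolar_trace(tg, 2 * v)
  out <- normalise_and_zero_time(tr)
  expect_equal(out$t, tg)
  expect_equal(out$v_real, v / v[1], tolerance = 1e-12)

  # a 16 ns echo-rise offset is recovered within one 8 ns step
  t2 <- seq(-0.04, 1.5, by = 0.008)
  echo <- exp(-((t2 - 0.016) / 0.05)^2) * exp(-0.2 * pmax(t2, 0))
  out2 <- normalise_and_zero_time(dipolar_trace(t2, echo))
  shift <- t2[length(t2) - length(out2$t) + 1]
  expect_lte(abs(shift - 0.016), 0.008 + 1e-12)

  # idempotence
  once <- normalise_and_zero_time(tr)
  twice <- normalise_and_zero_time(once)
  expect_equal(twice$t, once$t)
  expect_equal(twice$v_real, once$v_real, tolerance = 1e-12)

  # maximum at trace end
  expect_warning(normalise_and_zero_time(dipolar_trace(tg, tg + 1)), "trace end")
})

test_that("background fitting is exact on its own model", {
  tg <- default_t_grid()
  tr <- dipolar_trace(tg, 0.97 * exp(-0.05 * tg^(3.5 / 3)))
  tr$label <- "normalised"
  bg <- fit_background(tr, fit_start_us = 0.5)
  expect_equal(bg$amplitude, 0.97, tolerance = 1e-6)
  expect_equal(bg$k, 0.05, tolerance = 1e-6)
  expect_equal(bg$d, 3.5, tolerance = 1e-6)

  # flat trace with k and d pinned: amplitude is the mean
  fl <- dipolar_trace(tg, rep(0.8, length(tg)))
  fl$label <- "normalised"
  bgf <- fit_background(fl, fit_start_us = 0.5, d = 3, k = 0)
  expect_equal(bgf$amplitude, 0.8, tolerance = 1e-12)

  expect_error(fit_background(tr, fit_start_us = 5), "outside")
  short <- dipolar_trace(seq(0, 0.05, by = 0.008), rep(1, 7))
  short$label <- "normalised"
  expect_error(fit_background(short, fit_start_us = 0.01), "insufficient|outside")
})

test_that("background decay rate is recovered from a modulated trace", {
  # simulated trace: oscillations from 2.5 nm decay before the fit window
  ds <- make_dataset("s100", seed = 3, noise_ref = 0)
  d <- ds$design
  tr <- ds$traces[[4]]
  tr$label <- "normalised"
  bg <- fit_background(tr, d = d$bg_d)      # window default: 35% of t_max
  expect_equal(bg$k, d$bg_k, tolerance = 0.1)
})

test_that("divide_background is the identity for k = 0 and inverts the generator", {
  ds <- make_dataset("s100", seed = 3, noise_ref = 0)
  tr <- ds$traces[[8]]
  tr$label <- "normalised"
  idb <- divide_background(tr, background_model(0, 3, 1))
  expect_equal(idb$v_real, tr$v_real / tr$v_real[1], tolerance = 1e-12)
  expect_identical(idb$label, "background_corrected")

  ff <- divide_background(tr, background_model(ds$design$bg_k, ds$design$bg_d, 1))
  K <- dipolar_kernel(tr$t, default_r_grid())
  f_direct <- simulate_form_factor(
    gaussian_distribution(ds$design$dist_mean, ds$design$dist_sd),
    ds$truth$delta_true[8], K)
  expect_equal(ff$v_real, f_direct$v_real, tolerance = 1e-9)

  deep <- background_model(10, 6, 1)
  expect_error(divide_background(tr, deep), "underflow")
})

test_that("modulation depth extraction is exact, calibrated, and bounded", {
  tg <- default_t_grid()
  rg <- default_r_grid()
  K <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)

  # noise-free self-consistency at delta = 0.25
  f <- simulate_form_factor(g, 0.25, K)
  f$label <- "background_corrected"
  est <- extract_modulation_depth(f, g, K)
  expect_equal(est$delta, 0.25, tolerance = 1e-9)

  # flat trace: delta = 0 and the noise estimator reproduces sigma
  set.seed(9)
  fl <- dipolar_trace(seq(0, 1, length.out = 1000), rep(1, 1000))
  fl <- add_noise(fl, 0.02, seed = 21)
  fl$label <- "background_corrected"
  K2 <- dipolar_kernel(fl$t, rg)
  est2 <- extract_modulation_depth(fl, g, K2)
  expect_lt(est2$delta, 0.01)
  expect_equal(est2$noise_rms, 0.02, tolerance = 0.1)
})

test_that("noisy depth estimates agree with a Monte-Carlo oracle", {
  tg <- seq(0, 2.392, by = 0.008)[1:300]
  rg <- default_r_grid(dr = 0.05)
  K <- dipolar_kernel(tg, rg)
  g <- gaussian_distribution(2.5, 0.15, rg)
  f0 <- simulate_form_factor(g, 0.10, K)
  est <- vapply(1:200, function(s) {
    f <- add_noise(f0, 0.005, seed = 300 + s)
    f$label <- "background_corrected"
    extract_modulation_depth(f, g, K)$delta
  }, numeric(1))
  se <- stats::sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - 0.10), 3 * se)
})

test_that("sensitivity is the depth-to-noise ratio", {
  expect_equal(compute_sensitivity(0.2, 0.01), 20)
  expect_equal(compute_sensitivity(0, 0.03), 0)
  expect_error(compute_sensitivity(0.2, 0), "positive")
  # ProcessingResult invariant: sensitivity = delta / noise_rms exactly
  ds <- make_dataset("s100", seed = 2)
  res <- process_trace(ds$traces[[9]])
  expect_equal(res$sensitivity, res$delta / res$noise_rms, tolerance = 1e-12)
  expect_true(res$delta >= 0 && res$delta <= 1)
})

test_that("depth and sensitivity are invariant under trace scaling", {
  ds <- make_dataset("s100", seed = 2)
  tr <- ds$traces[[9]]
  tr5 <- tr; tr5$v_real <- 5 * tr5$v_real
  a <- process_trace(tr)
  b <- process_trace(tr5)
  expect_equal(b$delta, a$delta, tolerance = 1e-9)
  expect_equal(b$sensitivity, a$sensitivity, tolerance = 1e-9)
})

test_that("extracted depths rise monotonically with titrant at good SNR", {
  ds <- make_dataset("s100", seed = 6)
  rep <- run_pipeline(ds)
  s <- rep$samples[order(rep$samples$ligand_conc_M), ]
  expect_gte(mean(s$sensitivity), 10)
  expect_gt(stats::cor(s$delta, s$ligand_conc_M, method = "spearman"), 0.9)
})
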