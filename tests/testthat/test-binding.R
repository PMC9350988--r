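# 1:1 ligand-depletion isotherm: bound fraction, per-series and global fits,
# profile-likelihood confidence intervals.

test_that("fraction_bound matches its limits and the root-finding oracle", {
  expect_identical(fraction_bound(1e-7, 0, 7e-8), 0)
  # stoichiometric limit: K_D = 0 with ligand at or above protein
  expect_equal(fraction_bound(1e-7, 1e-7, 0), 1, tolerance = 1e-12)
  expect_equal(fraction_bound(1e-7, 5e-7, 0), 1, tolerance = 1e-12)

  # frozen oracle value (uniroot on the mass balance; spec quotes ~0.9919,
  # the oracle and the closed form both give 0.991327)
  expect_equal(fraction_bound(1e-7, 8.1e-6, 7e-8), 0.991327, tolerance = 1e-6)
  expect_equal(fraction_bound(1e-7, 8.1e-6, 7e-8), fb_root(1e-7, 8.1e-6, 7e-8),
               tolerance = 1e-10)
})

test_that("fraction_bound stays in [0,1] and agrees with uniroot on random sweeps", {
  set.seed(100)
  # range sweep: a million random triples across nine decades
  P <- 10^runif(1e6, -12, -3)
  L <- 10^runif(1e6, -12, -3)
  K <- 10^runif(1e6, -12, -3)
  f <- fraction_bound(P, L, K)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(fraction_bound(1e-7, 10^seq(-9, -4, 0.1), 7e-8)) >= 0))

  # per-point oracle on a random subsample (uniroot is scalar)
  idx <- sample.int(1e6, 2000)
  f_or <- mapply(fb_root, P[idx], L[idx], K[idx])
  expect_lt(max(abs(f[idx] - f_or) / pmax(f_or, 1e-300)), 1e-10)
})

test_that("predicted depths saturate and stay monotone", {
  L <- 10^seq(-8, -3, 0.25)
  expect_identical(predict_delta(1e-7, L, 7e-8, 0), rep(0, length(L)))
  d <- predict_delta(1e-7, L, 7e-8, 0.35)
  expect_true(all(diff(d) >= 0))
  expect_equal(predict_delta(1e-7, 1, 7e-8, 0.35), 0.35, tolerance = 1e-6)
})

test_that("noise-free isotherm parameters are recovered to 1e-6 relative", {
  L <- exp(seq(log(1e-7), log(8.1e-6), length.out = 10))
  d <- predict_delta(1e-7, L, 7e-8, 0.35)
  ser <- titration_series(1e-7, L, d, rep(1e-4, 10))
  fit <- fit_isotherm(ser)
  expect_equal(fit$kd, 7e-8, tolerance = 1e-6)
  expect_equal(fit$delta_max, 0.35, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-8)
  # interval invariants
  expect_true(fit$ci68_kd[1] <= fit$kd && fit$kd <= fit$ci68_kd[2])
  expect_true(fit$ci95_kd[1] <= fit$ci68_kd[1] && fit$ci68_kd[2] <= fit$ci95_kd[2])
})

test_that("degenerate and saturated series raise the ill-conditioned paths", {
  # two-point series (constructor invariant bypassed deliberately)
  ser2 <- titration_series(1e-7, c(1e-6, 8e-6), c(0.33, 0.34), c(0.01, 0.01),
                           validate = FALSE)
  expect_warning(fit_isotherm(ser2), "ill-conditioned|saturat")

  # everything saturated: kd only bounded from above
  L <- exp(seq(log(1e-6), log(1e-4), length.out = 6))
  d <- predict_delta(1e-7, L, 1e-9, 0.35)
  ser <- titration_series(1e-7, L, d, rep(0.01, 6))
  expect_warning(fit <- fit_isotherm(ser), "ill-conditioned")
  expect_true(fit$upper_bound_only)

  expect_error(titration_series(1e-7, c(1e-6, 2e-6), c(0.1, 0.2), c(0.01, 0.01)),
               "at least 4")
})

test_that("the 68% profile CI is calibrated over 200 seeds", {
  L <- exp(seq(log(1e-7), log(8.1e-6), length.out = 10))
  dtrue <- predict_delta(1e-7, L, 7e-8, 0.35)
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    dobs <- pmin(1, pmax(0, dtrue + rnorm(10, 0, 0.01)))
    f <- suppressWarnings(fit_isotherm(titration_series(1e-7, L, dobs, rep(0.01, 10))))
    f$ci68_kd[1] <= 7e-8 && 7e-8 <= f$ci68_kd[2]
  }, logical(1))
  expect_gte(mean(hits), 0.60)
  expect_lte(mean(hits), 0.76)
})

test_that("CI width shrinks as depth uncertainties shrink", {
  L <- exp(seq(log(1e-7), log(8.1e-6), length.out = 10))
  dtrue <- predict_delta(1e-7, L, 7e-8, 0.35)
  width <- vapply(c(0.02, 0.01, 0.005), function(se) {
    set.seed(31)
    dobs <- pmin(1, pmax(0, dtrue + rnorm(10, 0, se)))
    f <- suppressWarnings(fit_isotherm(titration_series(1e-7, L, dobs, rep(se, 10))))
    log10(f$ci68_kd[2]) - log10(f$ci68_kd[1])
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("consistency: dense noise-free-ish sampling recovers the truth", {
  L <- exp(seq(log(3e-8), log(3e-5), length.out = 100))
  set.seed(8)
  dobs <- pmin(1, pmax(0, predict_delta(1e-7, L, 7e-8, 0.35) + rnorm(100, 0, 0.002)))
  f <- fit_isotherm(titration_series(1e-7, L, dobs, rep(0.002, 100)))
  expect_equal(f$kd, 7e-8, tolerance = 0.1)
  expect_equal(f$delta_max, 0.35, tolerance = 0.01)
})

test_that("global fit: identity on replicates, recovery, misfit detection", {
  L <- exp(seq(log(1e-7), log(8.1e-6), length.out = 10))
  d <- predict_delta(1e-7, L, 7e-8, 0.35)
  ser <- titration_series(1e-7, L, d, rep(1e-4, 10))
  g <- global_fit(list(ser, ser))
  f1 <- fit_isotherm(ser)
  expect_equal(g$kd, f1$kd, tolerance = 1e-9)

  # parameter recovery across the three-series design with realistic SEs
  hits <- vapply(1:100, function(s) {
    set.seed(2000 + s)
    mk <- function(P, se) {
      dd <- pmin(1, pmax(0, predict_delta(P, L, 7e-8, 0.35) + rnorm(10, 0, se)))
      titration_series(P, L, dd, rep(se, 10))
    }
    gf <- suppressWarnings(global_fit(list(mk(1e-7, 0.01), mk(5e-8, 0.02),
                                           mk(5e-8, 0.02))))
    gf$kd > 7e-8 / 2 && gf$kd < 7e-8 * 2
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # sharing delta_max across deliberately different series must misfit
  set.seed(77)
  dA <- pmin(1, predict_delta(1e-7, L, 7e-8, 0.35) + rnorm(10, 0, 0.005))
  dB <- pmin(1, predict_delta(1e-7, L, 7e-8, 0.20) + rnorm(10, 0, 0.005))
  sA <- titration_series(1e-7, L, dA, rep(0.005, 10))
  sB <- titration_series(1e-7, L, dB, rep(0.005, 10))
  g_per <- suppressWarnings(global_fit(list(sA, sB), share_delta_max = FALSE))
  g_shr <- suppressWarnings(global_fit(list(sA, sB), share_delta_max = TRUE))
  expect_gt(g_shr$chi2_reduced, g_per$chi2_reduced)

  expect_error(global_fit(list(ser)), "at least 2")
})
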