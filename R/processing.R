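#' Phase-correct a quadrature-detected trace
#'
#' Rotates the complex signal \eqn{(v_r + i v_i) e^{-i\theta}} by the angle
#' that minimises the RMS of the imaginary channel over the trace tail
#' (default: last half), then fixes the sign so the real channel is
#' positive. For a noiseless rotation the closed-form solution is exact.
#'
#' @param trace A [dipolar_trace] with an imaginary channel. A purely real
#'   trace is returned unchanged.
#' @param tail_fraction Fraction of the trace (from the end) used to
#'   determine the angle.
#' @return A [dipolar_trace] labelled `"phased"`; the fitted angle in
#'   degrees is stored in `meta$phase_deg`.
#' @export
phase_correct <- function(trace, tail_fraction = 0.5) {
  stopifnot(inherits(trace, "dipolar_trace"))
  if (all(trace$v_real == 0) &&
      (is.null(trace$v_imag) || all(trace$v_imag == 0)))
    stop("degenerate input: all-zero signal")
  if (is.null(trace$v_imag) || all(trace$v_imag == 0)) {
    trace$label <- "phased"
    return(trace)
  }
  n <- length(trace$t)
  idx <- seq.int(max(1L, n - ceiling(tail_fraction * n) + 1L), n)
  vr <- trace$v_real[idx]; vi <- trace$v_imag[idx]
  if (all(vr == 0) && all(vi == 0)) stop("degenerate input: all-zero signal")
  # Im((vr + i vi) e^{-i theta}) = vi cos(theta) - vr sin(theta); minimising
  # its sum of squares is a 2x2 eigenproblem with closed-form angle.
  theta <- 0.5 * atan2(2 * sum(vr * vi), sum(vr^2) - sum(vi^2))
  rot <- complex(real = trace$v_real, imaginary = trace$v_imag) *
    exp(complex(imaginary = -theta))
  if (sum(Re(rot)) < 0) {
    theta <- theta + pi
    rot <- -rot
  }
  meta <- trace$meta
  meta$phase_deg <- theta * 180 / pi
  dipolar_trace(trace$t, Re(rot), v_imag = Im(rot), meta = meta, label = "phased")
}

#' Zero-time correction and normalisation
#'
#' Locates the echo maximum on a lightly smoothed copy of the real channel,
#' shifts the time axis so that maximum defines t = 0, discards earlier
#' points, and divides the amplitudes by the value at t = 0.
#'
#' @param trace A phased or real [dipolar_trace].
#' @param smooth_window Odd moving-average window (points) used only to
#'   locate the maximum.
#' @return A [dipolar_trace] labelled `"normalised"` with `t[1] = 0` and
#'   `v_real[1] = 1`. If the maximum falls on the last point a warning is
#'   issued and the first point is used instead.
#' @export
normalise_and_zero_time <- function(trace, smooth_window = 5L) {
  stopifnot(inherits(trace, "dipolar_trace"))
  v <- trace$v_real
  n <- length(v)
  sm <- if (n >= smooth_window && smooth_window > 1L) {
    f <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
    ifelse(is.na(f), v, as.numeric(f))
  } else v
  imax <- which.max(sm)
  if (imax == n) {
    warning("echo maximum at trace end; using first point as zero time")
    imax <- 1L
  } else if (imax > 1L) {
    # shift only on a significant echo rise: white noise must not drag the
    # zero time to the right on a trace that already starts at its maximum
    noise_sm <- stats::mad(diff(v)) / sqrt(2 * smooth_window)
    if (sm[imax] - sm[1] <= 2 * noise_sm) {
      imax <- 1L
    } else {
      imax <- min(which(sm >= sm[imax] - noise_sm))
    }
  }
  keep <- seq.int(imax, n)
  v0 <- sm[imax]                   # smoothed amplitude: less noise in the scale
  if (v0 == 0) stop("degenerate input: zero amplitude at zero time")
  vr <- v[keep] / v0
  vr[1] <- 1                       # definitionally 1 at the zero-time point
  dipolar_trace(trace$t[keep] - trace$t[imax], vr,
                v_imag = if (!is.null(trace$v_imag)) trace$v_imag[keep] / v0,
                meta = trace$meta, label = "normalised")
}

#' Fit a stretched-exponential background
#'
#' Fits \eqn{A e^{-k t^{d/3}}} to the trace tail (`t >= fit_start_us`) by
#' least squares and returns the model extrapolated over the full range.
#' `d` is free in \[1, 6\] by default (RIDME backgrounds deviate from
#' d = 3) or can be fixed. Starting values come from a log-linear scan over
#' `d`; the fit is refined in the linear domain with box constraints.
#'
#' @param trace A normalised [dipolar_trace].
#' @param fit_start_us Start of the fit window in us (default: 35% of
#'   t_max, before which dipolar oscillations from ~2.5 nm have decayed).
#' @param d Fix the dimensionality at this value (e.g. 3); `NULL` = free.
#' @param k Fix the decay rate (only `k = 0` is commonly useful); `NULL` =
#'   free.
#' @return A [background_model] with attributes `fit_start_us` and `rss`.
#' @export
fit_background <- function(trace, fit_start_us = NULL, d = NULL, k = NULL) {
  stopifnot(inherits(trace, "dipolar_trace"))
  if (trace$label != "normalised") stop("fit_background expects a normalised trace")
  t_max <- max(trace$t)
  if (is.null(fit_start_us)) fit_start_us <- 0.35 * t_max
  if (fit_start_us < min(trace$t) || fit_start_us >= t_max)
    stop("fit_start_us outside the time range")
  sel <- trace$t >= fit_start_us
  if (sum(sel) < 10L) stop("insufficient data: fewer than 10 points in fit window")
  tt <- trace$t[sel]; vv <- trace$v_real[sel]

  if (!is.null(k) && k == 0) {
    A <- mean(vv)
    bg <- background_model(0, if (is.null(d)) 3 else d, A)
    attr(bg, "fit_start_us") <- fit_start_us
    attr(bg, "rss") <- sum((vv - A)^2)
    return(bg)
  }

  ssq <- function(par) {           # par = (A, k, d)
    sum((vv - par[1] * exp(-par[2] * tt^(par[3] / 3)))^2)
  }
  # log-linear starts over a d scan
  d_scan <- if (is.null(d)) seq(1, 6, by = 0.5) else d
  vpos <- pmax(vv, 1e-12)
  best <- NULL
  for (dd in d_scan) {
    X <- tt^(dd / 3)
    co <- stats::coef(stats::lm(log(vpos) ~ X))
    cand <- unname(c(exp(co[1]), max(0, -co[2]), dd))
    if (is.null(best) || ssq(cand) < ssq(best)) best <- cand
  }
  # optimise only the free parameters; fixed ones stay pinned
  free <- c(TRUE, is.null(k), is.null(d))
  lower <- c(1e-6, 0, 1)[free]; upper <- c(Inf, Inf, 6)[free]
  if (!is.null(d)) best[3] <- d
  if (!is.null(k)) best[2] <- k
  expand <- function(p) { full <- best; full[free] <- p; full }
  ssq_free <- function(p) ssq(expand(p))
  opt <- stats::optim(best[free], ssq_free, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e4, maxit = 500))
  # polish once more from the optimum (L-BFGS-B can stall on flat valleys)
  opt2 <- stats::optim(opt$par, ssq_free, method = "L-BFGS-B",
                       lower = lower, upper = upper,
                       control = list(factr = 1e1, maxit = 500))
  par <- expand(if (opt2$value <= opt$value) opt2$par else opt$par)
  bg <- background_model(par[2], par[3], par[1])
  attr(bg, "fit_start_us") <- fit_start_us
  attr(bg, "rss") <- min(opt$value, opt2$value)
  bg
}

#' Divide out the background
#'
#' Pointwise division of a normalised trace by the background shape
#' \eqn{B(t)/B(0)}, renormalised to 1 at t = 0, yielding the form factor.
#'
#' @param trace A normalised [dipolar_trace].
#' @param bg A [background_model].
#' @return A [dipolar_trace] labelled `"background_corrected"`.
#' @export
divide_background <- function(trace, bg) {
  stopifnot(inherits(trace, "dipolar_trace"), inherits(bg, "background_model"))
  if (trace$label != "normalised") stop("divide_background expects a normalised trace")
  Bs <- evaluate_background(bg, trace$t) / bg$amplitude
  if (any(Bs < 1e-6)) stop("numerical underflow: background below 1e-6")
  v <- trace$v_real / Bs
  v <- v / v[1]
  out <- dipolar_trace(trace$t, v,
                       v_imag = if (!is.null(trace$v_imag)) trace$v_imag / Bs,
                       meta = trace$meta, label = "raw")
  out$label <- "background_corrected"
  out
}

#' Extract the modulation depth from a form factor
#'
#' Least-squares fit of \eqn{1 - \Delta + \Delta (K P)} to the
#' background-corrected trace with \eqn{P(r)} held fixed (from inversion or
#' simulation). The model is linear in \eqn{\Delta}, so the box-constrained
#' optimum on \[0, 1\] is closed-form. The noise level is the standard
#' deviation of the fit residuals.
#'
#' @param form_factor A background-corrected [dipolar_trace].
#' @param dist A [distance_distribution] on the kernel grid.
#' @param kernel A [dipolar_kernel] whose time grid matches the trace.
#' @return List with `delta`, `noise_rms`, `delta_se` (linear-model
#'   standard error of `delta`), and `residuals`.
#' @export
extract_modulation_depth <- function(form_factor, dist, kernel) {
  stopifnot(inherits(form_factor, "dipolar_trace"),
            inherits(dist, "distance_distribution"),
            inherits(kernel, "dipolar_kernel"))
  if (form_factor$label != "background_corrected")
    stop("extract_modulation_depth expects a background-corrected trace")
  if (length(form_factor$t) != length(kernel$t_grid) ||
      max(abs(form_factor$t - kernel$t_grid)) > 1e-9)
    stop("trace and kernel time grids differ")
  s <- as.vector(kernel$matrix %*% (dist$p * trapz_weights(dist$r)))
  x <- 1 - s                       # F = 1 - delta * x
  y <- 1 - form_factor$v_real
  sxx <- sum(x^2)
  if (sxx <= 0) stop("estimation failure: degenerate design (flat kernel response)")
  delta <- sum(x * y) / sxx
  delta <- min(1, max(0, delta))   # box-constrained optimum of the 1-D LS problem
  res <- form_factor$v_real - (1 - delta * x)
  noise_rms <- stats::sd(res)
  list(delta = delta, noise_rms = noise_rms,
       delta_se = noise_rms / sqrt(sxx), residuals = res)
}

# Separable nonlinear least squares over the complete trace model
# V(t) = exp(-k t^(d/3)) * (c0 + sum_j q_j K(t, r_j) dr),  c0, q >= 0,
# with smoothness penalty on q = delta * P. Outer Nelder-Mead over (k, d),
# inner non-negative LS; for noise-free data this reaches the exact global
# minimum, removing the residual background/distribution ambiguity the
# alternating refinement leaves behind.
snlls_polish <- function(trace, kernel, lambda, bg_d = NULL, start = c(0.1, 3.5)) {
  tt <- trace$t; vv <- trace$v_real
  dr <- mean(diff(kernel$r_grid))
  M <- cbind(1, kernel$matrix * dr)
  nq <- ncol(kernel$matrix)
  L <- cbind(0, second_difference(nq))          # no penalty on the offset
  t_ref <- max(tt)
  zeros <- numeric(nrow(L))
  warm <- new.env(parent = emptyenv())
  inner <- function(par) {                      # par = (k, d)
    Bs <- exp(-par[1] * tt^(par[2] / 3))
    z <- nnls_qr(rbind(M * Bs, lambda * L), c(vv, zeros), warm = warm)
    list(z = z, sse = sum((vv - Bs * (M %*% z))^2))
  }
  # outer search over (total decay at t_max, d): k and d are strongly
  # correlated through the mid-trace decay, and this parameterisation
  # straightens the valley so Nelder-Mead converges
  to_kd <- function(par) c(max(0, par[1]) / t_ref^(par[2] / 3), par[2])
  obj <- function(par) {
    if (par[1] < 0 || par[2] < 1 || par[2] > 6) return(1e10)
    inner(to_kd(par))$sse
  }
  start2 <- c(start[1] * t_ref^(start[2] / 3), start[2])
  resid_fn <- function(par) {                   # par = (K_total, d)
    par[1] <- max(0, par[1]); par[2] <- min(6, max(1, par[2]))
    kd <- to_kd(par)
    Bs <- exp(-kd[1] * tt^(kd[2] / 3))
    z <- nnls_qr(rbind(M * Bs, lambda * L), c(vv, zeros), warm = warm)
    vv - Bs * (M %*% z)
  }
  opt <- if (is.null(bg_d)) {
    o <- stats::optim(start2, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
    p <- lm_refine(o$par, resid_fn)             # vector-residual LM polish
    p <- compass_refine(p, obj)                 # kink-robust final descent
    list(par = to_kd(p))
  } else {
    o1 <- stats::optim(start2[1], function(K) obj(c(K, bg_d)), method = "Brent",
                       lower = 0, upper = 50, control = list(reltol = 1e-14))
    list(par = to_kd(c(o1$par, bg_d)))
  }
  fin <- inner(opt$par)
  z <- fin$z
  c0 <- z[1]; q <- z[-1]
  amp <- c0 + sum(q) * dr
  delta <- if (amp > 0) sum(q) * dr / amp else 0
  list(bg = background_model(opt$par[1], opt$par[2], amp),
       delta = delta, q = q,
       noise_rms = sqrt(fin$sse / max(1L, length(tt) - 3L)))
}

# Levenberg-Marquardt with finite-difference Jacobians on the residual
# vector; the scalar SSE is too noisy near the optimum for simplex/quasi-
# Newton methods once the residual approaches the solver tolerance.
lm_refine <- function(par, resid_fn, maxit = 40L) {
  r <- resid_fn(par)
  sse <- sum(r^2)
  mu <- 1e-6
  for (it in seq_len(maxit)) {
    J <- vapply(seq_along(par), function(j) {
      h <- max(1e-7, 1e-6 * abs(par[j]))
      pp <- par; pp[j] <- pp[j] + h
      pm <- par; pm[j] <- pm[j] - h
      (resid_fn(pp) - resid_fn(pm)) / (2 * h)
    }, numeric(length(r)))
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (tries in 1:8) {
      step <- tryCatch(solve(H + mu * diag(diag(H) + 1e-30), g),
                       error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      cand <- par - as.numeric(step)
      rc <- resid_fn(cand)
      sc <- sum(rc^2)
      if (sc < sse) {
        par <- cand; r <- rc
        conv <- sse - sc < 1e-16 * (1 + sse)
        sse <- sc; mu <- mu / 3
        improved <- TRUE
        if (conv) return(par)
        break
      }
      mu <- mu * 10
    }
    if (!improved) return(par)
  }
  par
}

# Standard error of delta from the full trace model V = A e^{-k t^(d/3)}
# (1 - delta (1 - m)): the naive form-factor SE ignores the strong
# delta/background correlation and understates the uncertainty several-fold.
delta_se_full <- function(trace, m, bg, delta, bg_d_fixed = FALSE) {
  tt <- trace$t; vv <- trace$v_real
  A <- bg$amplitude; k <- bg$k; d <- bg$d
  e <- exp(-k * tt^(d / 3))
  g <- 1 - delta * (1 - m)
  tpow <- tt^(d / 3)
  dlog <- ifelse(tt > 0, log(tt), 0)
  J <- cbind(e * g,                        # dA
             -A * tpow * e * g,            # dk
             if (!bg_d_fixed) -A * k * tpow * dlog / 3 * e * g,  # dd
             -A * e * (1 - m))             # ddelta
  rss <- sum((vv - A * e * g)^2)
  npar <- ncol(J)
  sigma2 <- rss / max(1L, length(tt) - npar)
  cv <- tryCatch(solve(crossprod(J)), error = function(e2) NULL)
  if (is.null(cv)) return(NA_real_)
  sqrt(sigma2 * cv[npar, npar])
}

# Compass (pattern) search: coordinate steps with geometric shrinking.
# Derivative-free and immune to the active-set kinks of the inner NNLS that
# stall simplex and Gauss-Newton methods near the optimum.
compass_refine <- function(par, obj, h = 0.01, h_min = 1e-10) {
  f0 <- obj(par)
  scale <- pmax(abs(par), 1)
  n <- length(par)
  dirs <- cbind(diag(n), -diag(n))
  if (n == 2L)                                   # diagonal moves navigate the
    dirs <- cbind(dirs, c(1, 1), c(-1, -1),      # correlated (decay, d) valley
                  c(1, -1), c(-1, 1))
  while (h > h_min) {
    moved <- FALSE
    for (j in seq_len(ncol(dirs))) {
      cand <- par + h * scale * dirs[, j]
      fc <- obj(cand)
      if (fc < f0) { par <- cand; f0 <- fc; moved <- TRUE; break }
    }
    if (!moved) h <- h / 2
  }
  par
}

# Full-model background refinement: least squares of
# V(t) ~ A exp(-k t^(d/3)) * (1 - delta (1 - m(t))) over the whole trace,
# with m = K P fixed and delta concentrated out (linear given the rest).
refit_background_full <- function(trace, m, bg_start, bg_d = NULL) {
  tt <- trace$t; vv <- trace$v_real
  x <- 1 - m
  obj <- function(par) {
    B <- par[1] * exp(-par[2] * tt^(par[3] / 3))
    z <- vv / B
    delta <- min(1, max(0, sum(x * (1 - z)) / sum(x^2)))
    sum((vv - B * (1 - delta * x))^2)
  }
  start <- c(bg_start$amplitude, bg_start$k, bg_start$d)
  free <- c(TRUE, TRUE, is.null(bg_d))
  if (!is.null(bg_d)) start[3] <- bg_d
  expand <- function(p) { full <- start; full[free] <- p; full }
  opt <- stats::optim(start[free], function(p) obj(expand(p)),
                      method = "L-BFGS-B",
                      lower = c(1e-6, 0, 1)[free], upper = c(Inf, Inf, 6)[free],
                      control = list(factr = 1e1, maxit = 1000))
  par <- expand(opt$par)
  bg <- background_model(par[2], par[3], par[1])
  attr(bg, "fit_start_us") <- attr(bg_start, "fit_start_us")
  n_par <- if (is.null(bg_d)) 4L else 3L        # (A, k, [d]) + delta
  list(bg = bg, noise_rms = sqrt(opt$value / max(1L, length(tt) - n_par)))
}

#' Modulation-depth-to-noise sensitivity
#'
#' The figure of merit for low-concentration PDS: the ratio of the dipolar
#' signal amplitude (modulation depth) to the experimental RMS noise.
#'
#' @param delta Modulation depth.
#' @param noise_rms RMS noise, > 0.
#' @return `delta / noise_rms`.
#' @export
compute_sensitivity <- function(delta, noise_rms) {
  if (any(!is.finite(noise_rms)) || any(noise_rms <= 0))
    stop("noise_rms must be positive")
  delta / noise_rms
}

#' Process a raw dipolar trace end to end
#'
#' Pipeline composite: phase correction (if complex), zero-time and
#' normalisation, stretched-exponential background fit and division,
#' Tikhonov inversion of the tail-estimated dipolar signal to obtain a
#' fixed \eqn{P(r)}, then the constrained modulation-depth fit. The
#' modulation depth is defined on the background-corrected, renormalised
#' form factor as the fitted asymptotic drop, making it comparable across
#' background decays.
#'
#' @param trace A raw [dipolar_trace].
#' @param r_grid Distance grid for the inversion (coarser grids are faster;
#'   depth extraction is insensitive to the grid step).
#' @param lambda Regularisation parameter, or `"auto"` for L-curve
#'   selection.
#' @param fit_start_us Background fit window start (default 35% of t_max).
#' @param bg_d Fix background dimensionality, or `NULL` (free).
#' @param refine Number of re-inversion passes after the first depth
#'   estimate (default 1).
#' @param polish Run the separable-nonlinear-least-squares polish of the
#'   complete trace model (exact for noise-free data, slower; default
#'   `FALSE`).
#' @param dist Optional fixed [distance_distribution] on `r_grid`; when
#'   supplied the per-trace inversion is skipped and the modulation depth
#'   is fitted against this distribution (see [process_series()]).
#' @param zero_time Run the echo-maximum search of
#'   [normalise_and_zero_time()] (`TRUE` for raw spectrometer data with a
#'   pre-echo rise). By default traces are taken as already zero-time
#'   corrected -- the trace contract -- and only rescaled, because under
#'   noise a maximum search on a trace that already starts at its maximum
#'   shifts it spuriously.
#' @return Object of class `processing_result`: `form_factor`,
#'   `background`, `delta`, `delta_se`, `noise_rms`, `sensitivity`,
#'   `fit_start_us`, `dist` (the inverted distribution), `lambda`.
#' @export
process_trace <- function(trace, r_grid = default_r_grid(dr = 0.05),
                          lambda = 1, fit_start_us = NULL, bg_d = NULL,
                          refine = 1L, polish = FALSE, dist = NULL,
                          zero_time = FALSE) {
  stopifnot(inherits(trace, "dipolar_trace"))
  tr <- trace
  if (!is.null(tr$v_imag) && any(tr$v_imag != 0)) tr <- phase_correct(tr)
  if (tr$label %in% c("raw", "phased")) {
    tr <- if (zero_time) normalise_and_zero_time(tr) else {
      v0 <- tr$v_real[1]
      if (v0 == 0) stop("degenerate input: zero amplitude at zero time")
      vr <- tr$v_real / v0
      vr[1] <- 1
      dipolar_trace(tr$t - tr$t[1], vr,
                    v_imag = if (!is.null(tr$v_imag)) tr$v_imag / v0,
                    meta = tr$meta, label = "normalised")
    }
  }
  bg <- fit_background(tr, fit_start_us = fit_start_us, d = bg_d)
  ff <- divide_background(tr, bg)
  kernel <- cached_kernel(ff$t, r_grid)

  # initial depth from the tail plateau of the form factor
  ntail <- max(5L, ceiling(0.2 * length(ff$t)))
  delta0 <- 1 - mean(utils::tail(ff$v_real, ntail))
  delta0 <- min(0.99, max(0.01, delta0))

  fixed_dist <- !is.null(dist)
  if (fixed_dist && (length(dist$r) != length(r_grid) ||
                     max(abs(dist$r - r_grid)) > 1e-9))
    stop("fixed dist must live on r_grid")
  est <- NULL
  noise_full <- NULL
  for (pass in seq_len(1L + max(0L, refine))) {
    if (!fixed_dist) {
      sig <- ff
      sig$v_real <- (ff$v_real - (1 - delta0)) / delta0
      if (identical(lambda, "auto")) lambda <- select_lambda(sig, kernel)
      dist <- tikhonov_invert(sig, kernel, lambda)
    }
    est <- extract_modulation_depth(ff, dist, kernel)
    if (est$delta > 0.01) delta0 <- est$delta
    # refine the background against the full model background x form factor;
    # the tail-only stretched-exponential fit is degenerate in (A, k, d) and
    # biases the plateau, which a joint fit with the current P(r) removes
    if (pass <= refine) {
      m <- as.vector(kernel$matrix %*% (dist$p * trapz_weights(dist$r)))
      full <- refit_background_full(tr, m, bg, bg_d)
      bg <- full$bg
      noise_full <- full$noise_rms
      ff <- divide_background(tr, bg)
    }
  }
  if (polish) {
    pol <- snlls_polish(tr, kernel, lambda, bg_d = bg_d,
                        start = c(bg$k, bg$d))
    bg <- pol$bg
    attr(bg, "fit_start_us") <- fit_start_us %||% 0.35 * max(tr$t)
    ff <- divide_background(tr, bg)
    if (!fixed_dist) {
      sig <- ff
      d0 <- max(pol$delta, 0.01)
      sig$v_real <- (ff$v_real - (1 - d0)) / d0
      dist <- tikhonov_invert(sig, kernel, lambda)
    }
    est <- extract_modulation_depth(ff, dist, kernel)
    noise_full <- pol$noise_rms
  }
  m_fin <- as.vector(kernel$matrix %*% (dist$p * trapz_weights(dist$r)))
  if (is.null(noise_full)) {
    B <- evaluate_background(bg, tr$t)
    noise_full <- stats::sd(tr$v_real - B * (1 - est$delta * (1 - m_fin)))
  }
  se_full <- delta_se_full(tr, m_fin, bg, est$delta,
                           bg_d_fixed = !is.null(bg_d))
  delta_se <- max(est$delta_se, se_full, na.rm = TRUE)
  structure(list(form_factor = ff, background = bg, dist = dist,
                 delta = est$delta, delta_se = delta_se,
                 noise_rms = noise_full,
                 sensitivity = compute_sensitivity(est$delta, noise_full),
                 fit_start_us = attr(bg, "fit_start_us"), lambda = lambda),
            class = "processing_result")
}

#' @export
print.processing_result <- function(x, ...) {
  cat(sprintf(paste0("<processing_result> delta = %.4f +/- %.4f, ",
                     "noise = %.4g, sensitivity = %.1f\n"),
              x$delta, x$delta_se, x$noise_rms, x$sensitivity))
  cat(sprintf("  background: A = %.4f, k = %.4g, d = %.2f (fit from %.3g us)\n",
              x$background$amplitude, x$background$k, x$background$d,
              x$fit_start_us))
  invisible(x)
}

#' Process a titration series with a shared distribution and dimensionality
#'
#' Within one pseudo-titration the spin pair (hence the distance
#' distribution) and the sample matrix (hence the background
#' dimensionality) do not change; only the modulation depth and the decay
#' rate may vary with titrant. Exploiting this, the highest-titrant
#' ("anchor") trace -- the best signal-to-noise sample -- is processed with
#' everything free; its inverted distribution and fitted dimensionality are
#' then held fixed for every trace of the series. This suppresses the
#' spurious modulation-depth floor that per-trace background freedom
#' produces at low occupancy.
#'
#' @param traces List of raw [dipolar_trace]s belonging to one series.
#' @param anchor Index of the anchor trace (default: last, i.e. highest
#'   titrant concentration).
#' @param ... Passed to [process_trace()] (`r_grid`, `lambda`,
#'   `fit_start_us`, `refine`, `polish`).
#' @param share_bg_d Hold the anchor's background dimensionality fixed for
#'   all traces (default `TRUE`).
#' @return List of `processing_result`s, one per trace; the anchor's result
#'   carries the shared distribution.
#' @export
process_series <- function(traces, anchor = length(traces), share_bg_d = TRUE,
                           ...) {
  stopifnot(length(traces) >= 1L)
  res_anchor <- process_trace(traces[[anchor]], ...)
  shared_dist <- res_anchor$dist
  shared_d <- if (share_bg_d) res_anchor$background$d else NULL
  out <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    out[[i]] <- if (i == anchor) res_anchor
    else process_trace(traces[[i]], dist = shared_dist, bg_d = shared_d, ...)
  }
  out
}
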