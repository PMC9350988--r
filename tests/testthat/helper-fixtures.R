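# Shared fixtures. Everything is generated in code; no binary data.

# brute-force orientation average: independent quadrature oracle for the
# dipolar kernel (uniform trapezoid; n defaults high enough for ~1e-9)
kernel_brute <- function(t, r, D = 52.04, n = 1e6) {
  x <- seq(0, 1, length.out = n + 1)
  f <- cos((3 * x^2 - 1) * 2 * pi * D / r^3 * t)
  (sum(f) - 0.5 * f[1] - 0.5 * f[n + 1]) / n
}

# Simpson-rule kernel oracle (vectorised over r for grid sweeps)
kernel_simpson <- function(t, r, D = 52.04, n = 4e4) {
  x <- seq(0, 1, length.out = n + 1)
  wts <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  omega <- 2 * pi * D / r^3
  vapply(omega, function(w) sum(wts * cos((3 * x^2 - 1) * w * t)) / (3 * n),
         numeric(1))
}

# mass-balance root-finding oracle for the bound fraction
fb_root <- function(P, L, K) {
  if (L == 0) return(0)
  g <- function(x) (P - x) * (L - x) - K * x
  x <- stats::uniroot(g, c(0, min(P, L)), tol = min(P, L) * 1e-12)$root
  for (i in 1:4) {                       # Newton polish to machine precision
    gp <- -(P - x) - (L - x) - K
    x <- min(min(P, L), max(0, x - g(x) / gp))
  }
  x / P
}

# small standard grids used across tests
tiny_t <- function() seq(0, 1.5, by = 0.01)
tiny_r <- function() seq(1.8, 4, by = 0.05)

# simulated noisy series dataset, memoised per seed
make_dataset <- local({
  cache <- list()
  function(which = "s100", seed = 1, noise_ref = NULL) {
    key <- paste(which, seed, noise_ref %||% "def")
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- default_designs(seed = seed)[[which]]
    if (!is.null(noise_ref)) d$noise_ref <- noise_ref
    ds <- generate_titration(d)
    cache[[key]] <<- ds
    ds
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
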