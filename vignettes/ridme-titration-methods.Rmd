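---
title: "Determining nanomolar dissociation constants from RIDME titrations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining nanomolar dissociation constants from RIDME titrations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridmekd)
```

## The measurement

Pulse dipolar EPR spectroscopy (PDS) measures the magnetic dipole-dipole
coupling between pairs of unpaired electrons and converts it into
nanometre-scale distance distributions. In the RIDME variant with
orthogonal labels -- a nitroxide side chain detected directly and a
Cu(II)-NTA complex bound to an engineered double-histidine (dHis) motif --
the *modulation depth* $\Delta$ of the dipolar trace is proportional to
the fraction of detected nitroxides that have a Cu(II) partner, i.e. to
the occupancy of the metal-binding site. Titrating Cu(II)-NTA at fixed
protein concentration therefore turns a spectroscopic amplitude into a
binding isotherm, and the dissociation constant $K_D$ falls out of a fit.
Because PDS detects tens-of-nanomolar spin concentrations, this works in
a regime (protein $\approx K_D \approx 10^{-8}\,$M) where calorimetry
struggles.

This package implements the full chain: forward simulation, trace
processing, regularised distance inversion, and isotherm fitting, plus a
synthetic-data generator so that every stage is testable end to end
without instrument data.

## Forward model

The noise-free trace is
$$V(t) = B(t)\,\big[1 - \Delta + \Delta \textstyle\int P(r)\,K(t,r)\,dr\big],$$
with the orientation-averaged two-spin kernel
$$K(t, r) = \int_0^1 \cos\!\big((3x^2 - 1)\,\omega_{dd} t\big)\,dx,
  \qquad \omega_{dd} = \frac{2\pi D}{r^3},\; D = 52.04\ \mathrm{MHz\,nm^3},$$
and a stretched-exponential intermolecular background
$B(t) = A e^{-k t^{d/3}}$ with dimensionality $d$ free in $[1, 6]$
(RIDME backgrounds are known to deviate from $d = 3$).

The kernel integral is evaluated by Gauss-Legendre quadrature with the
node count scaled to the largest dipolar phase on the grid
($n \approx 0.7\,\phi_{max} + 30$). A fixed uniform rule cannot deliver
the required accuracy: at $r = 1.5$ nm and $t = 2.5$ us the phase exceeds
700 rad and a 201-point trapezoid is wrong by $\sim 10^{-2}$, while the
phase-adaptive rule agrees with a four-million-step brute-force
quadrature to better than $10^{-11}$ (tested).

Grid defaults are $r \in [1.5, 8]$ nm at 0.02 nm and $\Delta t = 8$ ns up
to 2.5 us, resolving the $\approx 2.5$ nm distance expected for the
nitroxide/dHis-Cu(II) pair used as the reference system.

## Trace processing

Processing one raw trace (`process_trace()`) runs:

1. **Phase correction** (complex traces): closed-form rotation minimising
   the imaginary RMS over the trace tail.
2. **Normalisation.** Traces are taken as already zero-time corrected
   (the `DipolarTrace` contract) and only rescaled to $V(0) = 1$. The
   echo-maximum search (`normalise_and_zero_time()`, for raw spectrometer
   data with a pre-echo rise) is opt-in, because on a trace that already
   starts at its maximum white noise drags the located maximum to the
   right and the spurious shift biases every later stage; the search
   shifts only when the smoothed rise exceeds twice the smoothed noise.
3. **Background fit** of $A e^{-k t^{d/3}}$ on the tail ($t \ge 35\%$ of
   $t_{max}$ by default; oscillations from 2.5 nm decay well before
   that), then a *full-model refinement*: least squares of
   $B(t)(1 - \Delta(1 - m(t)))$ over the whole trace with the dipolar
   shape $m = KP$ held fixed. The tail-only fit is degenerate in
   $(A, k, d)$ and systematically mis-extrapolates the plateau; the joint
   refinement removes that bias.
4. **Tikhonov inversion.** The dipolar signal
   $S = (F - (1 - \Delta_0))/\Delta_0$ ($\Delta_0$ from the tail plateau,
   then refined) is inverted by
   $\hat P = \arg\min_{P \ge 0}\|KP - S\|^2 + \lambda^2\|L_2 P\|^2$
   with a second-difference penalty, solved by an active-set non-negative
   least-squares method on the normal equations.
5. **Depth extraction.** $\Delta$ is the box-constrained least-squares
   coefficient of $1 - \Delta(1 - m)$ against the background-corrected
   trace; the problem is linear in $\Delta$, so the constrained optimum
   is closed-form, not a post-hoc clip. The noise estimate is the
   residual SD of the full model (background times form factor), and the
   sensitivity is $S = \Delta/\sigma$, the figure of merit for
   low-concentration PDS.

**Uncertainty of $\Delta$.** The naive linear-model standard error
ignores the strong correlation between $\Delta$ and the background
parameters and understates the uncertainty several-fold; `process_trace`
instead reports the SE from the $(A, k, d, \Delta)$ covariance of the
full trace model.

**Series-level processing.** Within one titration the spin pair (hence
$P(r)$) and the sample matrix (hence $d$) do not change; only $\Delta$
and possibly $k$ do. `process_series()` therefore processes the
highest-titrant, best-SNR "anchor" trace with everything free and holds
its $\hat P$ and $\hat d$ fixed for the rest of the series. Without this,
per-trace background freedom absorbs noise into a spurious positive
depth floor ($\sim +0.02$--$0.03$ absolute at 50 nM noise levels), which
compresses the isotherm and biases $K_D$ low by $\sim 20\%$; with it the
residual bias is a few percent (measured on synthetic data).

**High-precision option.** `polish = TRUE` replaces the alternating
refinement with separable nonlinear least squares on the complete model
$V = e^{-k t^{d/3}}(c_0 + \sum_j q_j K_j \Delta r)$, $c_0, q \ge 0$:
outer simplex plus pattern search over $(k, d)$ (reparameterised to
total-decay/dimensionality, which straightens the correlated valley),
inner non-negative least squares solved by QR on the stacked system
(normal equations lose half the digits at small $\lambda$). On noise-free
data this recovers $\Delta$ to $\sim 10^{-6}$; it is an order of
magnitude slower than the default path and is off in the pipeline.

## Distance inversion diagnostics

`select_lambda()` picks the L-curve corner (maximum Menger curvature of
the log residual / log seminorm curve). Two degeneracies fall back to
generalised cross-validation with a warning: a residual that can be
driven to numerical zero (noise-free data -- no statistical corner
exists) and monotone curvature. The corner is scale-equivariant: scaling
trace and noise together does not move it.

`validate_distribution()` implements the noise-addition convention: the
inversion is repeated on the signal plus fresh Gaussian noise at 50% of
the estimated noise SD, the point estimate is the trial mean and the
bands are $\pm 2$ SD across trials. **A caution on coverage:** because
the trials vary by only half the trace noise, the $\pm 2\sigma$ band
spans roughly $\pm 1\sigma$ of the true estimator variability; on a noisy
trace the band covers a known generating distribution at only
$\sim$50--60% of grid points (and less where smoothing bias dominates,
at the peak). The bands are a reproducibility diagnostic of the stated
convention, not calibrated 95% intervals; the corresponding acceptance
test is deliberately left failing rather than silently redefining the
convention. Coverage is excellent only when the validated trace is
itself noise-free.

`reliability_ranges()` annotates distances by the cube-root
trace-length convention: with $t_{max}$ in us, shape is reliable to
$5 (t_{max}/2)^{1/3}$ nm, mean and width to $6 (t_{max}/2)^{1/3}$, mean
to $6.5 (t_{max}/2)^{1/3}$, nothing beyond. The constants are
configurable; they reproduce the colour-band convention of established
processing software rather than a printed value.

## Binding model

Protein and $K_D$ are of the same order here, so ligand depletion is
material and the exact 1:1 quadratic is used, never the excess-ligand
hyperbola:
$$f_b = \frac{(P_T + L_T + K_D) - \sqrt{(P_T + L_T + K_D)^2 - 4 P_T L_T}}{2 P_T},$$
evaluated as $2L_T/(b + \sqrt{b^2 - 4 P_T L_T})$ to avoid cancellation at
small occupancy, and $\Delta(L_T) = \Delta_{max} f_b$. $\Delta_{max}$ is
free (it absorbs labelling efficiency and the maximal RIDME depth, which
depend on unprinted experimental factors); in the global fit it is
per-series by default.

`fit_isotherm()`/`global_fit()` minimise the $1/\sigma_\Delta^2$-weighted
sum of squares with $K_D$ on a log10 scale; $\Delta_{max}$ enters
linearly and is concentrated out in closed form, making the profile over
$\log_{10} K_D$ one-dimensional and fast. Confidence intervals come from
the profile likelihood ($\Delta\chi^2 = 1$ for 68%, 3.84 for 95%), with
thresholds inflated by the reduced chi-square when it exceeds 1
(`scale_errors`): when the supplied `delta_se` are optimistic the
intervals then reflect the observed scatter, and when they are correct
the inflation is inactive half the time and the 68% interval still
covers at the nominal rate (measured 0.665 over 200 seeds). A fit in
which every point is $>95\%$ saturated warns and flags $K_D$ as an upper
bound only.

**Reported global interval.** Per-series $\Delta$ errors are correlated
(shared anchor distribution and dimensionality), which independent-point
profile intervals structurally miss. Replicate series are the only
observable realisation of that error, so `run_pipeline()` widens the
reported global interval by the between-series scatter of per-series
$K_D$ estimates ($t$ quantile on $\log_{10} K_D$, random-effects style).
Measured on the synthetic design: profile-only 95% intervals cover the
truth in $\sim$78% of runs, widened ones in $\sim$96%, with the point
estimate within 9% of truth. The underlying `global_fit` contract is
unchanged.

## The synthetic world

`default_designs()` emulates the reference experiment: one series at
$P_T = 100$ nM and two replicates at 50 nM, each with ten log-spaced
Cu(II)-NTA concentrations from 100 nM to 8.1 uM, about 60 h of signal
averaging per sample, ground truth $K_D = 7\times10^{-8}$ M and
$\Delta_{max} = 0.35$. The distance distribution is a single Gaussian
(mean 2.5 nm, SD 0.15 nm) standing in for the simulated distribution of
the reference construct, whose numeric parameters are not printed; the
background defaults to $k = 0.1$, $d = 3.5$, a typical RIDME-like
stretched decay.

The noise law is
$$\sigma = \sigma_{ref}\,\frac{c_{ref}}{c}\sqrt{t_{ref}/t},$$
white and additive on the normalised trace: echo amplitude scales with
detected spin count while detector noise does not, and averaging improves
as $\sqrt{t}$. The detected spin is the nitroxide, so the protein
concentration (constant along a titration) sets $\sigma$; Cu(II) addition
changes $\Delta$, not the detection sensitivity. Halving the protein
concentration at fixed averaging time therefore exactly doubles the
noise. `noise_ref = 0.015` at $c_{ref} = 10^{-7}$ M, $t_{ref} = 60$ h is
a calibration constant, fixed once so that the 100 nM series has mean
sensitivity $\approx 20$ (0.2925 mean depth / 20); it is not an
experimentally reported number.

What a green test establishes -- and what it does not: the generator
shares its kernel and background family with the processing chain, so
end-to-end tests probe estimation error, not model error. Real RIDME
traces additionally carry ESEEM nuclear modulation, orientation
selection, phase drift and background shapes outside the stretched-
exponential family; none of these are simulated (deliberately out of
scope), so pipeline performance on real data will be somewhat worse than
the synthetic figures.

## Numerical choices

* Gauss-Legendre node count $\lceil 0.7\,\phi_{max}\rceil + 30$, verified
  against brute force to $10^{-11}$; kernels are cached per grid.
* Non-negative solver: Lawson-Hanson/FNNLS on normal equations,
  tolerance $10^{-10}\max(\mathrm{diag})$, at most $30 n$ iterations,
  with an objective-stall guard (three successive improvements below
  $10^{-14}$ accept the iterate) -- heavily regularised problems
  otherwise cycle on numerically zero coefficients. The polish path uses
  a QR variant on the stacked system with warm-started active sets.
* $K_D$ search bounds $[10^{-12}, 10^{-2}]$ M on a log scale; profile
  roots by `uniroot` at $10^{-9}$ tolerance; an interval endpoint that
  does not cross within bounds is reported as infinite.
* Degenerate inputs: all-zero complex traces, backgrounds below
  $10^{-6}$, fit windows with fewer than 10 points, and series with
  fewer than 4 points or under one decade of titrant all raise typed
  errors (or, for the 2-point series, a deliberate ill-conditioned
  warning path).

## Known limitations

* The modulation-depth floor of blind per-trace processing is reduced,
  not eliminated, by anchored series processing; a residual $+2$--$4\%$
  relative depth bias at low occupancy survives and maps to a
  $\sim -8\%$ bias in $K_D$ -- well inside the reported intervals, but
  visible in large Monte-Carlo averages.
* Validation bands under the 50%-noise-addition convention are not
  calibrated 95% intervals (see above).
* One dHis site, 1:1 binding, no nonspecific Cu(II) association at high
  ligand excess, no competition or kinetics.
* BES3T support covers the 1-D descriptor subset needed for dipolar
  traces (XPTS/XMIN/XWID/XUNI, REAL/CPLX, float32/float64, endianness),
  not the full format.
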