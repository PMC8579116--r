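---
title: "State-dependent effective connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-dependent effective connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(statedcm)
```

Resting-state brain activity wanders among a small number of metastable
functional-connectivity states. A single effective-connectivity estimate for a
whole scan therefore averages over genuinely different coupling regimes.
`statedcm` decomposes windowed estimates of effective (directed) connectivity
into state-specific components. This vignette describes the generative models,
the estimation machinery, the tunable parameters, and the choices made where
the design was genuinely open.

## The model stack

**States.** A hidden Markov chain `z_t` with at most `K` states evolves at the
sampling rate. Conditional on `z_t = k`, the observed multichannel series
follows a multivariate autoregression of order `p`:

`y_t | z_t = k  ~  N( sum_l W_l^(k) y_{t-l},  Sigma^(k) )`.

Because the MAR coefficients summarise the cross-correlation (equivalently the
cross-spectrum) of the signal, these states are *functional connectivity
states*. The forward-backward posteriors `s_k(t) = p(z_t = k | Y)` give, for
any window `w_i`, the **occupation index** `u_k(i) = mean over t in w_i of
s_k(t)` — the fraction of the window spent in state k.

**Windowed spectral DCM.** For each sliding window the data feature is the
cross-spectral density (CSD), estimated parametrically from a MAR fit of the
mean-removed, Hann-tapered segment. The generative model is a linearised
neural + hemodynamic cascade: neural states obey `dx/dt = A x + v(t)` with a
stable coupling matrix `A` (Hz); each node's BOLD response is the balloon
model (vasodilatory signal, inflow, venous volume, deoxyhemoglobin, with the
static readout), linearised to a first-order frequency response `B_j(f)`. The
predicted CSD is

`G(f) = D S(f) gv(f) S(f)* D + ge(f) I`,
`S(f) = diag(B_j(f)) (i 2 pi f I - A)^{-1}`,

with power-law spectra `gv, ge` for the endogenous fluctuations and
observation noise and a diagonal gain `D = diag(exp(gain_j))` that absorbs
arbitrary per-node units (z-scored components have no common physical scale).
Self-connections are parameterised as `-0.5 exp(theta_ii)` so they are always
inhibitory. Inversion is variational Laplace: Gauss-Newton ascent on the free
energy with Levenberg-Marquardt regularisation, a single log-precision
hyperparameter updated by EM, and acceptance only of free-energy-increasing
steps.

**Hierarchical decomposition.** Window-wise posteriors over the A-parameters
enter a parametric-empirical-Bayes (PEB) GLM whose regressors are a constant
plus the occupation indices of the retained states:

`A_i = A0 + sum_k u_k(i) A_(k) + random effects`.

`A0` is the zero-occupation baseline (regressors are deliberately *not*
mean-centred; a centring option would change `A0` into the mean connectivity).
The effective connectivity *in* state k is `A0 + A_(k)`. A third PEB level
with design `X2 = [1 1; 1 -1]` yields group-common and group-difference
effects; Bayesian model reduction re-evaluates evidence and posteriors under
reduced priors analytically. Window size and overlap are selected by the log
Bayes factor of the state-regressor model over the constant-only (stationary)
model on the same windowed posteriors.

**Subtyping.** Individuals are compared by the L1 distance between their
occupation matrices, mapped to similarities by `max(d) - d`, and clustered by
Newman leading-eigenvector modularity optimisation on the weighted graph
(self-loops removed). Modules smaller than `min_module` (default 4) are
reported but flagged excluded.

## The simulator

`simulate_dataset()` generates the validation conditions: five subjects,
300 s at TR 0.8 s (375 samples), four nodes, three connectivity states with
20-s dwell epochs switching by a column-stochastic transition matrix, neural
dynamics integrated by exact discretisation (matrix exponential plus Van Loan
innovation covariance), and the full nonlinear balloon model for the BOLD
readout with additive observation noise; each node is mean-centred.

Numerical choices that matter:

* **Hemodynamic integrator.** The balloon model is integrated in log space
  for positivity with a linearly implicit matrix-exponential (Rosenbrock)
  step and an analytic per-node Jacobian, driven by the neural series at the
  neural integration step (default 0.1 s), not a zero-order hold at the TR.
  An explicit Runge-Kutta step fails here: whenever sustained negative
  neural drive pushes inflow toward zero (`x < -gamma`), the log-flow
  equation becomes stiff and escapes in finite time regardless of step
  size. Log states are additionally bounded to ±5 (flow and volume can
  neither vanish nor grow without limit physiologically), which removes the
  numerical escape while leaving the regular regime untouched.
* **Fluctuation amplitude.** The endogenous fluctuation spectral amplitude
  defaults to `sigma = 0.02` (per node, white). The network's slow
  eigenmodes amplify input strongly, so this yields BOLD excursions of about
  1% signal change — a realistic amplitude that also keeps inflow away from
  the shut-off regime. State discriminability is carried by the spectral
  *shape*, which is amplitude-invariant, so the small default costs nothing
  for state estimation. Observation noise defaults to `obs_sd = 0.05`
  (about 5% of signal sd), appropriate for denoised component time series.
* **Initial state** of each path is uniform; each subject gets an
  independent path and noise stream derived from the master seed.

What the simulator does *not* emulate: scanner drift and motion artefacts,
spatially correlated physiological noise, inter-subject variability in
hemodynamics or connectivity (all subjects share the ground-truth matrices),
and non-Markovian dwell-time distributions. Passing recovery tests on these
data therefore demonstrates internal consistency of the estimation stack
under the stated conditions, not robustness to empirical artefacts.

## Estimation choices

**HMM-MAR.** Inference is EM (scaled forward-backward E-step; M-step by
responsibility-weighted regression) rather than the variational-Bayes scheme
of the original toolbox: downstream analyses consume only state probabilities
and occupation indices, which EM supplies with far less machinery. Three
refinements of plain maximum likelihood proved necessary:

* The M-step is *maximum a posteriori* with a fixed zero-mean Gaussian prior
  on every MAR coefficient (`w_prior`, default precision 10, i.e. prior sd
  about 0.3 on coefficients of z-scored data). Each state must estimate
  about `p n^2` coefficients from a few hundred samples; without shrinkage
  the restarts overfit and the EM landscape is littered with poor optima
  (label accuracy against planted regimes caps near 0.55), while this mild
  prior roughly doubles the quality of the best reachable basins. Because
  the prior is fixed and occupancy-independent, much larger values make
  states without distinctive evidence collapse — the rich-get-richer pruning
  of variational treatments — and an optional inverse-Wishart-style
  covariance floor (`sigma_nu`) strengthens that pruning; both strong
  settings merge genuinely distinct states and are off by default. With a
  coefficient prior the exact M-step couples target dimensions through the
  innovation covariance; the update solves the resulting
  Kronecker-structured normal equations so the penalised objective is
  monotone (asserted at every iteration).
* Responsibilities are initialised from random *contiguous blocks* (about 15
  segments per series) rather than i.i.d. random weights, which start EM at
  the symmetric saddle where all states are identical.
* Among the converged restarts the pipelines select by *consensus*: the run
  whose hard state path agrees best with the other runs after optimal label
  matching. On planted-state benchmarks this stability criterion tracks true
  segmentation quality distinctly better than the likelihood (agreement
  correlates ~0.9 with label accuracy), which can prefer runs that overfit
  a lucky split. Selection by objective or by the number of states shared by
  every subject remains available.

The first `p` samples of each series carry no lagged evidence; their
probability rows are set to the stationary distribution and flagged invalid,
and occupation indices simply exclude them from window means. Convergence is
a relative objective change below `1e-6` (at most 500 iterations); the
default 30 restarts keep the bundled study inside a few minutes at modest
risk of a poorer optimum than an exhaustive search.

**Spectral layer.** Windows are 0-based half-open `[start, start + size)`
with only full windows kept. The default frequency grid is 32 uniform bins
from the window fundamental `1/window length` to `min(0.25, Nyquist)` Hz —
the resting-state band at these sampling rates. Per-window processing order
is mean-remove, Hann taper, MAR fit (order 5 by default, matching the HMM),
parametric CSD with the `delta * H Sigma H*` convention (so auto-spectra
integrate to process variance).

**Inversion.** Priors: off-diagonal couplings and self log-scalings
`N(0, 1/16)` — coupling magnitudes up to ~0.5 Hz are plausible a priori, and
a tighter prior visibly shrinks large true couplings toward zero and costs
credible-interval calibration; hemodynamic log-scalings `N(0, 1/256)`; gains
and noise parameters `N(0, 1/64)` with spectral-exponent prior mean 1
(pink). Two data conditioning steps stabilise the fit: the observed CSD is
rescaled per node so its mean auto-power matches the prior-mean prediction
(residual unit mismatch lands in the gain posteriors), and residuals are
weighted per frequency by the inverse observed mean auto-power, floored at
10% of its peak — a bounded multiplicative-error (Whittle-style) weighting.
Without the weighting the steeply coloured low-frequency bins dominate the
sum of squares and the estimated precision collapses; without the floor the
bins far below the hemodynamic passband, which carry mostly
spectral-estimation noise, are amplified to parity with the informative
band. Convergence: free-energy change below `1e-4` on four
consecutive iterations, at most 128 iterations; a single precision
hyperparameter is shared across frequencies. The reported posterior is the
best accepted iterate, so the recorded free-energy trace is non-decreasing
by construction.

**PEB.** Between-unit covariance is a single scaled identity `exp(gamma) I`
with a `N(-2, 4)` prior on `gamma`, estimated by maximising the exact
marginal evidence (the posterior over effects is closed-form given `gamma`).
Second-level effects have prior `N(0, 1)`. For a *saturated* group design
(two groups with common + difference regressors) the between-unit variance is
fixed at zero — there are no residual degrees of freedom, and uncertainty is
propagated from the lower level. Fixed-effects group mode (concatenating all
subjects' windows per group) is the default; random-effects PEB-of-PEB is
available via per-subject fits.

**Thresholding.** An effect "survives" at 95% posterior confidence when the
probability that it has the sign of its mean exceeds 0.95 strictly
(`|mean| > 1.645 sd`); exact ties are excluded. Credible-interval coverage of
ground truth uses two-sided 95% intervals; diagonal entries are compared
after the monotone `-0.5 exp()` transform, with interval endpoints mapped
through the same transform.

## Known limitations

* Coupling *magnitudes* from short windows are compressed/expanded along
  weakly identified directions (gain/self-decay trade-offs); recovery is
  assessed by correlation and interval coverage, not absolute magnitude.
* The window-selection log Bayes factor compares models on the same windowed
  posteriors for a given pair; comparisons *across* pairs inherit the usual
  caveat that the data representation changes with the window size.
* The subtype module optimises Newman modularity on the full weighted
  similarity graph; no sparsification or consensus across resolutions is
  attempted.
* With `K = 1` or a single retained state the occupation regressor is
  collinear with the constant; only the sum `A0 + A_(k)` is then
  identified.

## Problem sizes used in the bundled validation

The shipped study (`run_simulation_study()`) uses the full conditions: five
subjects of 375 samples, HMM with `K = 5`, order 5 and 30 restarts, 11
windows of 75 samples (overlap 45) per subject, 55 window inversions of the
lean 4-node model, and a fixed-effects PEB over all 55 windows. Unit and
property tests use smaller planted problems (2 nodes, 1-2 states, a few
hundred samples) whose expected values come from closed forms, brute-force
oracles, or long-run simulations.
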