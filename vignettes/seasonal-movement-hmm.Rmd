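---
title: "Seasonal two-state hidden Markov movement models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal two-state hidden Markov movement models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`seasonhmm` fits a population-level, two-state hidden Markov movement model
to daily GPS-collar tracks of ungulates. Each animal-year — one animal's
locations within a biological year running July 1 (day 1) to June 30 (day
365) — is an independent time series; all animal-years are completely
pooled into one model. The latent state on day $t$ is either short-distance
local movement (SDLM, state 1) or long-distance movement (LDM, state 2).

**Observation model.** The daily step length $s_t$ (km, distance between
consecutive 06:00 locations) and turning angle $\theta_t$ (radians,
deviation from the previous bearing, counterclockwise positive, in
$(-\pi,\pi]$) are conditionally independent given the state:

$$s_t \mid Z_t = i \sim \mathrm{Gamma}(\alpha_i, \beta_i), \qquad
  \theta_t \mid Z_t = i \sim \mathrm{wrappedCauchy}(\mu_i, \kappa_i).$$

The gamma distribution is parameterized by its mean $m_i$ and standard
deviation $\sigma_i$ ($\alpha_i = m_i^2/\sigma_i^2$, $\beta_i =
m_i/\sigma_i^2$), and the state-2 mean is tied to state 1 by $m_2 = m_1 +
\delta$ with $\delta > 0$, which identifies the labels (state 2 always has
the larger steps) and removes label switching structurally rather than by
post hoc relabeling.

**State model.** The state process is a time-inhomogeneous Markov chain
with day-specific transition matrix

$$\Gamma_t = \begin{pmatrix} 1-\gamma_{12}(t) & \gamma_{12}(t) \\
  \gamma_{21}(t) & 1-\gamma_{21}(t) \end{pmatrix}, \qquad
  \mathrm{logit}\,\gamma_{ij}(t) = \beta^0_{ij} + f_{ij}(t),$$

where $f_{ij}$ is a penalized spline in day of the biological year with $K
= 5$ knots evenly spaced on $[1, 365]$ and random-effects coefficients
$b_{ijk} \sim \mathrm{Normal}(0, \sigma_{b,ij})$. The matrix applied on the
move from day $t-1$ into day $t$ is $\Gamma$ evaluated at day $t$; which of
the two endpoints indexes the step is a convention, fixed here once and
used consistently by the likelihood, the simulator and the marginal-curve
propagation.

The initial state of each animal-year record gets a categorical
distribution $\phi_d$ shared by all records starting on the same day $d$,
with a Dirichlet(1, 1) prior.

**Likelihood.** The latent states are marginalized with the forward
algorithm (scaled at every step, so a 365-day series cannot underflow).
Days without a usable step or turn — collar gaps, plus the structurally
undefined first step and first two turns of every record — contribute an
emission density of 1, while the day's transition still applies; this is
exact marginalization of the missing observations, not imputation.

## Priors

| parameter | prior | notes |
|---|---|---|
| $m_1$, $\delta$, $\sigma_1$, $\sigma_2$ | Normal$(0, 10)$ truncated to $(0,\infty)$ | km; diffuse at step-length scale |
| $\mu_1$, $\mu_2$ | Uniform$(-\pi, \pi]$ | circular means |
| $\kappa_1$, $\kappa_2$ | Uniform$(0, 1)$ | wrapped-Cauchy concentrations |
| $\beta^0_{12}$, $\beta^0_{21}$ | Normal$(0, 2)$ | logit scale |
| $\sigma_{b,12}$, $\sigma_{b,21}$ | Normal$(0, 10)$ truncated to $(0,\infty)$ | spline-coefficient SDs |
| $b_{ijk}$ | Normal$(0, \sigma_{b,ij})$ | hierarchical |
| $\phi_d$ | Dirichlet$(1, 1)$ | per record-start day |

## Spline basis

The construction the seasonal trend cites is a random-effects spline; the
basis itself is not uniquely pinned down by that description, so
`build_basis()` implements the low-rank radial form
$Z = Z_{\mathrm{raw}}\,\Omega^{-1/2}$ with $Z_{\mathrm{raw}}[d,k] = |d -
\kappa_k|^3$ and $\Omega[k,l] = |\kappa_k - \kappa_l|^3$ (matrix square
root via SVD), under which iid-normal coefficients induce a thin-plate-type
smoothness penalty. Two purely numerical normalizations are applied and
recorded in `formulation_tag`:

* columns are centered (their means move into the intercept, which
  decorrelates $\beta^0$ from $b$ in the posterior), and
* columns are rescaled to unit sample SD, so $\sigma_b$'s prior acts on a
  common scale instead of the raw cubic magnitudes ($\sim 10^6$).

Neither changes the family of seasonal curves, only its coordinates. A
cubic B-spline alternative (`type = "bspline"`) is provided as a
plug-point; everything downstream is basis-agnostic. No periodicity
constraint is imposed: July 1 and June 30 values may differ, deliberately.
Because the basis is not guaranteed to be the one used with any particular
published fit, equivalence with external results should be judged at the
level of fitted seasonal curves, not coefficients.

## Sampler

`sample_posterior()` runs adaptive blocked random-walk Metropolis on the
marginalized likelihood (the forward pass is compiled C++; emission
densities are cached so transition-parameter updates do not recompute
them). Design choices that matter:

* **Sampling scales.** Positive parameters on the log scale, probabilities
  on the logit scale, with exact Jacobians; priors act on the natural
  scale. Turning-angle means are sampled as offsets from a reference
  direction estimated at initialization, so a posterior concentrated at the
  $\pm\pi$ wrap point (typical for SDLM states, which tend to reverse
  direction) does not straddle a discontinuity.
* **Blocks.** Step-emission (4), angle-emission (4), and one block per
  transition ($\beta^0_{ij}$, the $K$ coefficients, and
  $\log\sigma_{b,ij}$), plus one scalar per record-start-day $\phi_d$
  (only the affected series are re-evaluated). Transition blocks are cheap
  and get several sweeps per iteration.
* **Non-centered coefficients + interweaving.** The spline coefficients
  are sampled as $u = b/\sigma_b$ (non-centered), which removes the funnel
  when the seasonal signal is weak; an interweaved centered-scale update of
  $\sigma_b$ with $b$ held fixed (free: the likelihood does not move)
  breaks the $u$–$\sigma_b$ ridge that appears when the signal is strong.
  Together these keep the potential scale reduction factors of all
  transition parameters near 1 at both the 5-series smoke scale and the
  100-animal-year study scale.
* **Adaptation.** Per-block proposal covariances are adapted during
  burn-in (empirical covariance scaled by $2.38^2/d$ with a Robbins–Monro
  global-scale correction toward 0.234/0.44 acceptance) and frozen at the
  end of burn-in, so retained draws come from a fixed-kernel Markov chain.
* **Initialization.** A 2-group k-means split of the observed step lengths
  seeds the emission parameters (means, SDs, circular means and resultant
  lengths per group); spline coefficients start at 0 and $\phi_d$ at 0.5;
  chains add small jitter. Starts with non-finite posterior are redrawn a
  bounded number of times.
* **Defaults.** 3 chains × 20,000 iterations, 10,000 burn-in, thinning 5 —
  6,000 retained draws. The study-scale analyses in `analysis/` and the
  test suite use 3 × 4,000 (2,000 burn-in, thin 5; 1,200 draws), which the
  Gelman–Rubin diagnostic (< 1.1 for every parameter) supports at the
  100-animal-year problem size.

Whole-run reproducibility is exact: one integer seed drives data
generation and all chains.

**Diagnostics.** `gelman_rubin()` implements the classic potential scale
reduction factor $\sqrt{\hat V/W}$ with $\hat V = \frac{n-1}{n}W +
(1+\frac1m)\frac{B}{n}$ (the degrees-of-freedom correction some
implementations add is omitted; the two agree to ~10⁻³ at realistic sizes,
and the test suite cross-checks against `coda`). Turning-angle means are
diagnosed on angular deviations from their pooled circular mean — a chain
sitting exactly at the $\pm\pi$ wrap would otherwise inflate the statistic
without any convergence failure. `hpdi()` is the empirical Chen–Shao
interval: the narrowest window $(x_{(i)}, x_{(i+\lceil 0.9n\rceil)})$ of
the sorted draws, lowest start on ties.

## Seasonal summaries

The marginal probability of being in the LDM state on day $t$ is computed
per posterior draw by Chapman–Kolmogorov propagation $p_t = p_{t-1}
\Gamma_t$ from day 1. The anchor is the day-1 initial-state distribution
when some record starts on day 1, else $(0.5, 0.5)$; the propagation rule's
starting point is a modeling choice, recorded here and in the output
metadata.

Seasonal events are defined on the first derivative of that curve: fall
start = first local maximum of the derivative, fall end = first subsequent
local minimum, spring start/end = the second such pair. The derivative uses
central finite differences after a 7-day centered moving average
(configurable; edges shrink the window), and extrema must clear a
topographic-prominence floor of 0.005/day so sub-noise wiggles cannot spawn
events. Extrema in the first `guard_days` (default 10) of the year are
ignored: the propagation relaxes from its day-1 anchor toward the seasonal
level over a few days — roughly $1/(\gamma_{12}+\gamma_{21})$ — and that
transient would otherwise register as the year's first event. The guard
also means a genuine switching event in the first week of July cannot be
detected; for these scenarios (and the ungulate systems they caricature)
none occurs there. Both parameters are recorded in the call; events whose required
predecessor never occurs in a draw are flagged undefined rather than
invented, and the undefined fraction is reported. Event days are computed
per draw and then summarized (median, 90% HPDI), propagating posterior
uncertainty into the timing estimates. Derivative-of-median mode is
available by applying `curve_derivative()`/`event_days()` to the median
curve directly; the per-draw route is the default because it is the one
that yields interval-valued event days.

## The synthetic-data generator

`preset_scenario()` encodes two stylized studies:

* **deer_like** — strongly seasonal migrants: bimodal $\gamma_{12}$
  (autumn and spring switching pulses with a deep winter trough), high
  winter $\gamma_{21}$ (long-distance bouts are short-lived), step means
  0.66/7.12 km, SDs 0.57/6.49 km, turning angles centered at $\pi$/0 with
  concentrations 0.26/0.70, 8% missing steps.
* **pronghorn_like** — variable winter movers: a single early-winter
  $\gamma_{12}$ peak, uniformly low $\gamma_{21}$, smaller LDM steps
  (1.17/3.64 km, SDs 0.947/3.04 km), a diffuse LDM turning-angle
  distribution ($\kappa_2 = 0.12$), under 1% missingness.

Emission values sit at published point estimates for the two species the
scenarios caricature. The seasonal truths are built by sketching the target
switch-probability curves at anchor days, then least-squares projecting
their logits onto the $K=5$ basis; the *projected* curve is the recorded
truth, so the truth lies inside the model family and parameter recovery is
well-defined. Records start on days 1–30 (collars deployed near July 1; the
pool is configurable for mid-year deployments) and run through day 365;
initial states are drawn with $P(\mathrm{SDLM}) = 0.9$, animals mostly
starting the year on summer range. Missingness is injected as run-length
gaps (geometric lengths, mean 2 days) whose start rate is calibrated so the
expected missing-step fraction matches the scenario rate; steps and turns
adjacent to a gap go missing exactly as the preprocessing rules dictate.
`emit_raw_fixes()` dead-reckons 2-hourly planar fixes consistent with the
daily series (the 06:00 fix exact, sub-daily fixes interpolated with 20 m
jitter), so the whole preprocessing path can be tested end to end.

What the generator does *not* emulate — and what passing tests therefore do
not certify about real collar data: positional error and fix-quality
screening, habitat- or weather-driven covariate effects, among-individual
and among-year heterogeneity (the model itself pools completely), diel
structure within days, and non-planar terrain. The generator draws from the
exact parametric families the model assumes, so recovery tests validate the
inference machinery, not the model's adequacy for any real population.

## Numerical choices and degenerate inputs

* Steps under 1 m are floored at 0.001 km (simulator and preprocessing
  alike): a zero step has zero gamma density, and sub-meter daily
  displacement is below collar precision.
* Feb 29 shares Feb 28's day index, so every biological year has exactly
  365 days; ties in 06:00 resampling keep the earlier fix.
* Planar (projected-CRS, meters) coordinates are the primary path; a
  geodesic mode (`geosphere` great-circle distances and forward azimuths)
  handles lon/lat input. Which one a given published analysis used is
  generally unknowable from coordinates alone; neither is asserted as
  canonical.
* Animal-years with fewer than 3 daily fixes are rejected with a
  diagnostic; a single all-missing day has likelihood exactly 1; proposals
  that produce non-finite likelihoods are rejected rather than crashing the
  chain.
* Problem sizes: the shipped analyses and tests use 100 animal-years
  (deer-like) and 60 (pronghorn-like) with 3 × 4,000-iteration chains, and
  smaller smoke/coverage studies (5–15 animal-years, 8 replicates); these
  sizes were chosen so the complete pipeline reruns comfortably on a single
  CPU while leaving the diagnostics unambiguous.

## Known limitations

Exactly two states, by design — short-distance vs long-distance movement is
not the same thing as residency vs migration, and behaviors like
pre-migration ranging inflate the LDM state. No covariates beyond day of
year; no among-year or among-individual variation; no model comparison over
the number of states or knots ($K = 5$ fixed a priori). The marginal-LDM
propagation starts from a modeling-choice anchor, and event timing depends
(weakly, via the smoothing window and prominence floor) on two configurable
constants. Forward–backward smoothing probabilities are deliberately not
provided; the post hoc summary is forward propagation, and `viterbi_decode()`
exists for synthetic-data accuracy checks rather than as an inferential
endpoint.
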