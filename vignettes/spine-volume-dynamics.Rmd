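---
title: "Modelling dendritic spine volume dynamics as a drift-diffusion process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dendritic spine volume dynamics as a drift-diffusion process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

## The model

Dendritic spines carry most excitatory synapses, and a spine's head volume
$V$ (in $\mu m^3$) is a stable correlate of the strength of its synapse. In
longitudinal two-photon imaging of adult mouse visual cortex, spine volumes
fluctuate from session to session; `spinedyn` models those fluctuations as a
one-dimensional Itô diffusion

$$dV(t) = \mu(V)\,dt + \sigma(V)\,dW(t),$$

with time measured in units of one imaging interval (2 days; $W$ has unit
variance per interval) on the volume range $[V_{min}, V_{max}] =
[0.01, 1.0]\ \mu m^3$. Both coefficient laws are linear in $V^{2/3}$, the
surface-area proxy — in adult neocortex the fluctuation amplitude scales with
the spine surface rather than with its volume, which makes small spines
relatively quieter and hence longer-lived than a multiplicative
(volume-proportional) model would predict:

* slow (day-scale) fluctuation: $\sigma_{slow}(V) = a\,V^{2/3} + b$,
* fast (minute-scale) fluctuation: $\sigma_{fast}(V) = 0.115\,V^{2/3} + 0.0051$,
* drift: $\mu(V) = -0.12\,V^{2/3} + 0.029$.

The fast component reflects actin-driven volume breathing and measurement
noise. It does not accumulate: it rides on top of the slow state as
observation noise, so only $\sigma_{slow}$ drives long-term behaviour. The
wild-type parameterization has $a = 0.198$; the *Fmr1* knockout (a fragile X
model) differs **only** in that slope factor, $a = 0.278$ — a single number
capturing its destabilized spines. Both intercepts come from anchoring the
fitted line at the smallest-bin point ($V = 0.015$, $\sigma = 0.02$):
`anchored_intercept(0.198)` $= 0.0081$ and `anchored_intercept(0.278)`
$= 0.0033$.

```{r specs}
wt_spec()
drift_zero_crossing(wt_spec())  # spines below ~0.12 um^3 tend to grow
```

## Stationary distribution and elimination

With reflecting boundaries at both ends the Fokker–Planck equation

$$\partial_t p = \tfrac12 \partial_V^2\!\left[\sigma^2(V)\,p\right]
  - \partial_V\!\left[\mu(V)\,p\right]$$

has the closed-form stationary density
$f(V) = C\,\sigma^{-2}(V) \exp \int 2\mu(V)/\sigma^2(V)\,dV$, which
`stationary_density()` evaluates by cumulative trapezoidal quadrature on a
uniform grid (4001 nodes by default; the mean changes by $<10^{-4}\ \mu m^3$
under grid doubling). The density is unimodal with a heavy small-volume
shoulder; its mean is about $0.133\ \mu m^3$ for the wild type and
$0.136\ \mu m^3$ for the knockout — the knockout's steeper slope sharpens the
small-volume peak *and* fattens the large-volume tail, leaving the mean
almost unchanged, which is why group differences in mean volume are so easy
to miss experimentally.

```{r stationary}
d <- stationary_density(wt_spec())
stationary_mean(d)
```

Spine elimination is modelled as absorption at $V_{min}$, starting from the
stationary density. `elimination_rate()` offers three routes:

* **`"interval"`** (default): one Gaussian drift-diffusion transition per
  2-day imaging interval, with mass at or below $V_{min}$ at the session
  counted as eliminated. This is the model at the resolution at which both
  the coefficient laws were estimated and elimination is scored in
  time-lapse imaging (a spine is "eliminated" when it is missing at the next
  session, not when its latent volume grazes a threshold between sessions).
  It yields 3.8% per 2 days for the wild type and about 6.9% for the
  knockout.
* **`"fpt"`**: continuous-time first passage, by Crank–Nicolson integration
  of the Fokker–Planck equation with an absorbing (Dirichlet) lower
  boundary. This counts sub-threshold excursions between sessions as well
  and is therefore systematically larger (about 5.7% and 10.4%).
* **`"sde"`**: Monte-Carlo first passage by Euler–Maruyama simulation with a
  Brownian-bridge boundary correction; it is the stochastic oracle for
  `"fpt"` and agrees with it within sampling error.

The distinction matters: the two first-passage routes answer "did the latent
volume ever touch $V_{min}$", the interval route answers "was the spine gone
at the next session". Only the latter corresponds to the measured per-2-day
turnover, and it is the route the headline model predictions come from.

```{r elimination}
elimination_rate(wt_spec(), t = 1, method = "interval")
```

## Estimating the laws from longitudinal tables

The estimation chain mirrors how such data are analysed in practice:

1. `pair_transitions()` forms per-spine volume changes between sessions a
   fixed interval apart; pairs ending in an elimination are excluded from
   moment estimation (the end volume does not exist) and counted separately.
2. `bin_moments()` sorts transitions by starting volume and pools
   consecutive groups of 32 (30 for 10-min data). Per bin it reports the
   mean change $\mu_j$ and the SD $\sigma_j$ about it with the population
   divisor $N_j$, the median member volume as the bin's representative
   volume, a $\chi^2$-pivot 95% interval for $\sigma_j$ (df $= N_j$) and the
   SEM of $\mu_j$. A trailing remainder smaller than half a bin merges into
   the last full bin.
3. `fit_fast()` fits $\sigma$ against $V^{2/3}$ on 10-min data (drift fixed
   at zero — minute-scale mean changes are negligible).
4. `decompose_slow()` applies $\sigma_{slow} =
   \sqrt{\max(\sigma^2 - \sigma_{fast}^2, 0)}$ bin-wise, flagging clipped
   bins.
5. `fit_anchored_slope()` fits the single slope of $\sigma_{slow}$ vs
   $V^{2/3}$ through the anchor $(0.015^{2/3}, 0.02)$; the anchor pins the
   smallest spines, whose behaviour dominates turnover.
6. `fit_drift()` fits $\mu_j$ vs $V^{2/3}$ unconstrained, pooling groups
   (the drift is indistinguishable between genotypes).
7. `compare_slopes()` tests a group difference through a no-intercept linear
   model on the pooled anchored coordinates with a group-by-abscissa
   interaction; Mann–Whitney (per-dendrite elimination fractions) and
   Kolmogorov–Smirnov (volume distributions) wrappers complete the
   comparisons.

`estimate_cohort()` chains steps 1–6 and assembles fitted
`drift_diffusion_spec` objects per group; `run_full_pipeline()` adds the
simulation and prediction stages around it.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: two groups at the published
scale (754 and 878 spines on 15/20 dendrites in 5 mice each), five sessions
2 days apart. Initial latent volumes are drawn from each group's stationary
density. Between sessions the latent volume advances, by default, by **one
Gaussian drift-diffusion increment per interval** (mean $\mu(V)$, SD
$\sigma_{slow}(V)$, reflection at $V_{max}$, elimination when the session
endpoint falls at or below $V_{min}$). This makes the per-interval increments
follow the fitted laws exactly — which is what the laws describe, since they
were estimated from per-interval changes — and makes generated turnover match
`elimination_rate(method = "interval")`. A `sampling = "diffusion"` option
instead integrates the continuous SDE through the interval with
first-passage absorption; note that under the continuous dynamics the
restoring drift contracts the SD of per-interval changes a few percent below
$\sigma_{slow}(V)$, so the two modes answer subtly different questions and
the interval mode is the faithful emulator of the fitted model.

Each observation adds independent truncated-at-zero Gaussian noise with SD
$\sigma_{fast}(V)/\sqrt{2}$. The $\sqrt{2}$ is deliberate:
$\sigma_{fast}$ is defined as the SD of *changes* between two closely spaced
observations, i.e. of a difference of two independent noises, so the
per-observation noise must carry half the variance. With this convention
10-min differences reproduce the fast law exactly and 2-day observed changes
have variance $\sigma_{slow}^2 + \sigma_{fast}^2$, matching the
decomposition. A `mode = "fast"` cohort freezes the latent state and samples
7 time points 10 minutes apart; `mode = "fixed"` emulates the fixed-tissue
control (no fluctuation at all). There is no spine-formation process: the
model has no source term (an optional `topup` keeps cohort size constant by
adding fresh stationary spines, off by default).

What the generator does **not** emulate: filopodia and their exclusion
rules, hierarchical dendrite/animal variance components (labels are assigned
round-robin; the model has none), imaging artifacts, registration error, or
detection-level elimination calls. Passing the parameter-recovery tests
therefore shows the pipeline is a faithful implementation of the published
procedure on data that satisfy the model's assumptions — not that the
procedure is unbiased on real images.

## What the self-consistency loop reveals

Applying the full estimation chain to cohorts generated from the model
itself does *not* return the generating slope: it returns about 15% less
(roughly 0.17 for a generating 0.198, with matching attenuation for the
knockout), reproducibly across replicates. The package's tests measure this
rather than hide it, and three mechanisms account for it, all faithful to
the published procedure:

* transitions that end in elimination are excluded, truncating the lower
  tail of $\Delta V$ precisely in the small-volume bins;
* reflection at $V_{max}$ compresses changes in the largest bins;
* observation noise smears the bin abscissa (regression to the mean) and
  the fast-variance subtraction is evaluated at the noisy bin volume.

The same mechanisms act on the real data the laws were fitted from, so the
published slope factors are themselves pipeline outputs, not instantaneous
SDE coefficients; simulating them and re-estimating compounds the
attenuation once more. The recovered *drift* law is steepened analogously
(regression to the mean), although its zero crossing survives near
$0.12\ \mu m^3$. Group *differences* are unaffected in practice: the
wild-type/knockout slope interaction is detected essentially always at study
scale.

## Numerical choices

* **Fokker–Planck solver**: Crank–Nicolson on the conservative (flux) form,
  so the discrete nodal mass is conserved exactly (telescoping fluxes) under
  reflecting (zero-flux) boundaries; absorbing boundaries are a Dirichlet
  row at $V_{min}$. Survival is the conserved-mass ratio of the scheme
  itself; at an absorbing wall the first node's cell is bisected, its inner
  half counting as absorbed at $t = 0^+$ — this makes the elimination
  functional effectively grid-flat (changes $\sim 0.002$ percentage points
  under grid doubling at the default 4000 nodes $\times$ 2000 steps).
  Crank–Nicolson is not L-stable: stiff modes oscillate rather than damp for
  large steps, so solver defaults keep $\Delta t \le 0.02$ intervals and
  point initial conditions are deposited as a narrow Gaussian (3 grid
  cells), not a true delta.
* **SDE integrator**: Euler–Maruyama under the Itô convention (coefficients
  at the pre-step state, clamped to the domain), default
  $\Delta t = 0.005$ intervals; reflection by folding; absorption applies a
  Brownian-bridge within-step crossing probability, removing the
  $O(\sqrt{\Delta t})$ endpoint bias so Monte-Carlo and PDE first passage
  agree within binomial error at $10^5$ paths.
* **Sphere profile**: the PSF-blurred-ball intensity reduces exactly — the
  free axial integral contributes $\sqrt{2\pi}\sigma_z$ — to a single radial
  integral with a Bessel kernel, evaluated by adaptive quadrature at
  relative tolerance $10^{-6}$ with exponential scaling for numerical
  stability; the reduction is validated in the tests against direct 2-D
  quadrature and 4-D Monte-Carlo integration. Sphere fits are unweighted
  Levenberg–Marquardt least squares with the PSF widths fixed
  ($\sigma_x = 0.24\ \mu m$, $\sigma_z = 0.91\ \mu m$, i.e. 0.56 and
  2.1 $\mu m$ FWHM).
* **Problem sizes**: test and acceptance computations use cohorts at the
  published scale (up to ~900 spines, 5 sessions), $10^4$–$10^5$
  Monte-Carlo paths, 2000–8001 density nodes, and 30–100 replicate cohorts
  for the recovery and power measurements — sizes at which every stochastic
  tolerance was calibrated against its analytic or oracle counterpart.

## Known limitations

* The estimator attenuation described above means fitted specs from
  `estimate_cohort()` should not be read as unbiased SDE coefficients.
* The elimination threshold equals $V_{min}$ exactly; detection-level
  censoring (dim spines missed by an observer) is not modelled.
* Time-independent coefficients only; no spine-formation source term, so
  simulated cohorts shrink (or use `topup`).
* The $2/3$ exponent is fixed by design, not estimated (the empirical
  sublinearity is close to, but not exactly, $2/3$).
* The per-day vs per-2-day ambiguity in the drift's published units is
  resolved as per-interval throughout; the doubled-drift alternative is
  grossly inconsistent with the published elimination predictions.
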