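---
title: "Measuring transcription-factor activity by repression and fitting promoter input integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription-factor activity by repression and fitting promoter input integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(araLogic)
```

## The problem

The four promoters of the *E. coli* arabinose regulon — P~araBAD~, P~araC~,
P~araE~ and P~araFGH~ — all listen to the same two regulators, AraC (active
when bound to arabinose) and CRP (active when bound to cAMP), yet produce
distinct expression patterns. Understanding how each promoter *integrates*
the two inputs normally requires binding constants, intracellular
concentrations and reaction rates that are hard to measure and harder to
relate to in-vivo conditions.

The alternative implemented here sidesteps biochemistry: a *repression
reporter* is a constitutive promoter with the transcription factor's
operator cloned immediately downstream, so factor binding shows up as
*loss* of an otherwise constant luminescent signal. Reading repression
rather than activation avoids the promoter-specific, non-linear
polymerase–activator interactions that make activation-based reporters
hard to interpret. Three such reporters are used: synARA (AraC operator),
synCRP (CRP operator) and synRNAP-σ^70^, the bare constitutive promoter,
which reads polymerase activity itself.

## The activity model

Reporter expression $S$ (luminescence counts per second divided by OD600,
a per-cell proxy) follows a single-operator repression law

$$S = \frac{\alpha_{\mathrm{rep}}}{1 + A} + T,$$

where $A \ge 0$ is the dimensionless activity of the cognate factor,
$\alpha_{\mathrm{rep}}$ is the reporter's activation rate (by definition
the span between fully unrepressed and fully repressed expression) and
$T$ its basal (fully repressed) level. Inverting,

$$A = \frac{\alpha_{\mathrm{rep}}}{S - T} - 1,$$

clamped below at 0 (expression above the unrepressed level would give a
negative activity) and above at a configurable cap (default 50), because
the inversion diverges as $S \to T$. The exact algebraic form of the
repression law is a modelling choice — the hyperbolic single-operator
form is used because its inverse goes negative exactly when
$S - T > \alpha_{\mathrm{rep}}$, which matches the normalize-to-zero
convention, and because it is the standard form in the repression
literature. It is isolated behind `repression_forward()` /
`infer_activity()` so a Hill variant would be a one-line swap.

Two readings of the basal level are possible: the repressed reporter's own
plateau (default, estimated by `calibrate_reporter()` as a robust minimum)
or a scaled σ^70^-channel value; both are supported, and the default is
the one that keeps each reporter self-contained.

## Input integration at steady state

With measured activities $A^*$ (AraC–arabinose), $C^*$ (CRP–cAMP) and
polymerase activity $\sigma$, promoter expression at steady state is
modelled additively over the promoter's bound states:

$$B = \sigma\,(\alpha A^* + \beta C^* + \gamma A^* C^*) + T_B ,$$

with $\alpha$ = transcription due to AraC alone, $\beta$ = CRP alone,
$\gamma$ = both together, and $T_B$ basal transcription. Because the
synthetic operators bind their factors with different affinity than the
natural promoters, the fitted coefficients absorb that binding ratio:
they are *relative* input strengths, not absolute activation rates. An
`occupancy` variant that divides the weighted sum by the bound-state
partition $1 + A^* + C^* + A^*C^*$ is available behind the `form`
argument; the additive form is the default and the one used everywhere.

`fit_integration_model()` estimates the coefficients by nonlinear least
squares (Levenberg–Marquardt, started at the ordinary-least-squares
solution on the additive regressors, with a final exact Gauss–Newton
step; for the additive form the problem is linear in its parameters and
the fit equals the OLS solution to better than $10^{-8}$). Standard
errors and two-sided t-tests against zero use the Jacobian at the
optimum with $n - p$ degrees of freedom. `reduce_and_compare()` removes
every coefficient insignificant at the chosen level (default 0.05; the
basal term is never removed), refits, and compares full and reduced
models by residual standard error and AIC. The AIC convention is the
Gaussian one with the error variance counted as a parameter,
$n \ln(\mathrm{RSS}/n) + 2(k+1)$; conventions differ by an additive
constant, which cancels in comparisons. Whether the published analysis
fitted or pinned $T_B$ is not stated; the package fits it as a free
intercept by default and accepts a pinned value.

For the four arabinose promoters the reference coefficient sets shipped
in `ara_coefficients()` have significant $\alpha$ and $\gamma$ and no
$\beta$ term: cAMP–CRP alone drives no detectable transcription, but it
amplifies AraC-driven transcription — AND-like logic with an
AraC-only bypass.

## Dynamics during diauxic shift

During growth on glucose plus arabinose, glucose exhaustion triggers a
sharp, transient pulse of CRP–cAMP activity followed by an exponential
rise of AraC–arabinose activity. Promoter expression then obeys

$$\frac{dB}{dt} = \sigma(t)\,(\alpha A^*(t) + \beta C^*(t) + \gamma
A^*(t) C^*(t)) + T_B - \mu B,$$

where $\mu$ is first-order loss. For long-lived proteins loss is
dilution by growth, $\mu = \ln 2 / \tau$ with $\tau$ the cell-cycle time
(estimated by log-linear OD regression, `estimate_tau()`); a protein with
a degradation constant of $8.33\times10^{-4}\,\mathrm{min}^{-1}$ loses
only 0.02499 per 30-minute cell cycle, so degradation is negligible
beside dilution. AraC itself is short-lived and uses
$\mu = \ln 2/\tau + k_{\mathrm{deg}}$ with the reported
$k_{\mathrm{deg}} = 0.0833\,\mathrm{min}^{-1}$ — taken verbatim even
though a 60-minute half-life would arithmetically give
$\ln 2 / 60 \approx 0.0116\,\mathrm{min}^{-1}$; the discrepancy is
documented here rather than resolved, and `loss_model()` accepts any
constant.

`integrate_expression()` solves the ODE with fixed-step classical RK4 on
the 4-minute measurement grid, sub-stepped 4× and driving signals
interpolated linearly between readings. The drivers are piecewise-linear
measurements and $\mu$ is small, so no stiff machinery is warranted; the
solver is validated against the constant-input closed form to $10^{-6}$,
shows the expected ≥4× error reduction per step halving, and cross-checks
against an adaptive solver (`deSolve::lsoda`) in the tests. The initial
condition defaults to the first observed expression value where an
observation exists (the pipeline) and to the basal steady state
$T_B/\mu$ otherwise.

Glucose-exhaustion timing varies between replicate experiments, so
`align_and_average()` shifts each replicate so that time zero sits 20
minutes before the detected rise in synCRP activity, then resamples to a
common grid and averages pointwise. Rise detection is a verbal rule made
precise: baseline mean + 3 SD over the first 5 points, exceeded for 2
consecutive readings. Activities are computed per replicate and then
averaged — the inversion is nonlinear, so the order matters; averaging
afterwards matches the per-experiment normalization described for the
underlying assays. `evaluate_prediction()` scores RMSE, peak-timing
error, and the observed/predicted peak ratio (the statistic behind the
observation that one promoter's measured expression ran about two-fold
above prediction).

## What the synthetic-data generator emulates

No plate-reader datasets are deposited with the study this package
operationalizes, so `simulate_gradient_plate()` and
`simulate_diauxic_experiment()` generate data with the statistical
structure the analysis assumes, with known ground truth:

* **Gradient plates** — one well per (arabinose, cAMP) combination, at
  most 96 (default 12 × 8 levels over 0–0.2% and 0–1 mM), read at
  4-minute intervals for 90 minutes with the 44-minute read treated as
  steady state. True activities come from a dose–response map:
  step-like Hill for AraC ($h = 4$, half-saturation 0.02%), graded
  Michaelis form for CRP (half-saturation 0.25 mM), constant $\sigma$;
  defaults span activities of roughly 0–3 so that fitted coefficients sit
  at the magnitudes of the reference sets. Expression is held at its
  steady value across the read window; the approach to steady state is
  not modelled.
* **Diauxic shifts** — 7 replicates by default, glucose exhaustion at
  60 ± 12 min (uniform jitter, seeded), a piecewise-exponential CRP
  pulse (rise 6 min, decay 10 min) centred on each replicate's
  exhaustion time, and a saturating-exponential AraC rise starting 10
  minutes later. Both shapes are phenomenological stand-ins: the source
  material shows them only as figures, so the generator uses the
  minimal smooth forms with independent time scales. Promoter channels
  are produced by integrating the dynamic model itself with the
  reference coefficients.
* **Noise** — multiplicative lognormal on luminescence (default sdlog
  0.05) and additive Gaussian on OD600 (default 0.002, floored at a
  small positive value); no noise model is stated in the source
  material, so these are conventional plate-reader choices. Zero sigmas
  reproduce the forward models exactly, and every draw flows from an
  explicit seed.
* **Growth** — OD600 is generated independently of expression (logistic
  for gradients; exponential–lag–exponential for diauxic shifts). There
  is no growth–expression feedback and no mechanistic glucose, PTS or
  adenylate-cyclase state: exhaustion exists only through the activity
  profiles.

Passing the recovery tests on these data therefore demonstrates that the
*analysis machinery* is correct and self-consistent — inversion inverts,
fits recover generating coefficients, the reduction drops structurally
absent terms, the ODE reproduces its own forward simulations — not that
real plate-reader data obey the generator's noise or pulse shapes.

## Numerical choices and degenerate inputs

* Activity cap 50 and OD floor 0.01: the inversion diverges at basal
  expression and early-time OD readings are unreliable; capped and
  floored values are flagged, never silently propagated.
* Expression at or below basal maps to the cap with a warning;
  expression above the unrepressed level maps to 0 (the
  normalize-to-zero rule).
* Zero-residual fits report AIC $-\infty$ with a warning rather than an
  error; rank-deficient designs (constant activities) raise a
  singular-fit error.
* No non-negativity constraint is imposed on coefficients; a significant
  negative estimate triggers a warning but is reported.
* Steady state is a single configurable read (default 44 min), not a
  window average; the windowed alternative would be a trivial extension
  but is not the default because the reference analysis reads one time.

## Problem sizes

The shipped defaults — 96-well gradients, 50-replicate stochastic
recovery studies, 200-replicate model-selection studies, 7-replicate
diauxic simulations on a 4-minute/180-minute grid — were chosen as the
sizes the corresponding bench experiment actually has, and they keep
every check in the test suite and the acceptance script within seconds
on a single core.

## Known limitations

* The pulse and rise shapes, the dose–response map and the noise model
  are stand-ins; conclusions about real data require recalibrating them.
* The repression law assumes one effective operator and no
  cooperativity; reporters built from tandem degenerate operators may
  deviate.
* AraC's repressive role at P~araC~'s O₁ site is not modelled, matching
  the scope of the reference analysis, which notes the resulting misfit
  at high arabinose.
* The occupancy form is provided for exploration but has not been
  calibrated against any dataset.

## A worked example

```{r example, eval = FALSE}
cal <- reporter_calibration(alpha_rep = 1, basal_T = 0.02)
sim <- simulate_gradient_plate(gradient_design(), ara_coefficients()$ParaBAD,
                               cal, cal, noise = noise_model(seed = 1))
tab <- steady_state_table(sim$plate, sim$layout, cal, cal, "ParaBAD")
full <- fit_integration_model(tab)
reduce_and_compare(tab, full)
```

The full chain, including the diauxic prediction, is one call:
`run_pipeline(list(seed = 1, outdir = "out"))`.
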