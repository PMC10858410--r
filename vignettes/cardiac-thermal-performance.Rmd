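---
title: "Cardiac thermal performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac thermal performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotherm)
```

## The assay and its indices

The package analyses stepwise cardiac thermal-performance assays in larval
fish. Anaesthetized larvae are warmed through an ordered series of
temperature steps (by default 9–25 °C: 2 °C increments to 19 °C, then 1 °C
increments to 25 °C, twelve steps in all), held 5 min at each step and
filmed for 2.5 min, so each step represents 7.5 min of residence. From each
larva's heart-rate-versus-temperature profile the package derives the
standard indices:

* **f~H0~** — heart rate at the first step (bpm);
* **f~Hpeak~**, **T~peak~** — the maximum measured heart rate and the
  temperature eliciting it (a sublethal upper-limit proxy);
* **Δf~Hpeak−H0~** — cardiac scope, the rise from initial to peak rate;
* **df~H~/dT** — the slope of heart rate on temperature below the
  breakpoint;
* **T~AB~** — the Arrhenius breakpoint temperature: the temperature where
  the slope of log~10~ f~H~ against inverse absolute temperature
  (1000/K) changes, a proxy for the thermal optimum;
* **T~Arr~** — the lowest temperature at which cardiac arrhythmia
  (discontinuous beating) appears, a near-lethal upper-limit proxy.
  Individuals still beating rhythmically at the final step carry a
  right-censored T~Arr~.

## The synthetic population generator

Real assay datasets are rarely shareable at will, and every downstream
stage needs data with the right statistical structure, so the generator is
a first-class, tested component rather than a fixture. Each of the four
anchor quantities (f~H0~, T~AB~, T~peak~, T~Arr~) follows a linear mixed
structure

y = intercept + slope · incubation + clutch effect + individual deviate,

with clutch effects shared across incubation groups (full-sibling clutches
are split across treatments) and independent Gaussian deviates per
individual. Draws violating the physiological ordering
T~AB~ < T~peak~ < T~Arr~ (or a non-positive f~H0~) are rejected and redrawn
(budget 1000). Resampling rather than truncation was chosen to avoid the
stronger marginal distortion truncation produces; rejection still induces a
small conditioning bias in the marginal means (order 0.1 °C at the default
SDs), which is why the law-of-large-numbers checks in the test-suite use
configurations where the rejection probability is negligible.

Defaults are calibrated once to the published larval longfin smelt assay:
fixed-effect intercepts and incubation slopes from the reported mixed-model
estimates (e.g. T~AB~: 9.13 + 0.63 · incubation °C), individual SDs from
group SEMs scaled by √n (T~AB~ 2.2, T~peak~ 2.2, T~Arr~ 1.1, f~H0~ 4.4),
and clutch SDs from the spread of reported clutch means (1.2, 0.9, 0.8,
3.5). Group sizes default to the study's 121/152/134 larvae incubated at
9/12/15 °C across five clutches — 407 individuals, 4884 rows.

The curve template is piecewise: linear in Arrhenius coordinates
(x = 1000/(T + 273.15) K, y = log~10~ f~H~) with slope −3.0 below T~AB~
(which reproduces the reported ~6 bpm/°C rise from ~55 bpm at 9 °C),
continuous at T~AB~ with the slope attenuated by a factor 0.35 up to
T~peak~, then a linear decline in °C of 4 bpm/°C to T~Arr~, beyond which
steps are arrhythmic with missing heart rate. Pre-breakpoint linearity is
imposed in Arrhenius space because that is the space in which T~AB~ is
estimated; the generative form is otherwise unconstrained by the
literature, and the post-peak decline is linear in °C purely for
simplicity. The latent T~Arr~ is continuous; the observed T~Arr~ is the
first protocol step at or above it, reproducing the discretization of the
assay. Observation noise is additive Gaussian on f~H~ (default SD 1.5 bpm,
truncated positive) — beat-count error is approximately additive in bpm,
and no within-individual error magnitude is published, so the default is
documented as arbitrary.

What the generator does **not** emulate: fluctuating-temperature regimes,
survival/hatching differences between treatments, heteroscedastic or
autocorrelated measurement error, and any T~peak~/T~Arr~ dependence beyond
the rejection-enforced ordering. Passing tests therefore demonstrate
correctness of the estimators under the assumed structure, not robustness
to every feature of real recordings.

```{r generator}
cfg <- population_config(n_per_group = c(30, 30, 30), seed = 1)
sim <- generate_dataset(cfg)
validate_dataset(sim$data)
```

## The measurement layer

`synth_trace()` renders a beat train as Gaussian pulses (default width
0.06 s) sampled at 30 frames/s plus white noise; `detect_beats()` recovers
beats by matched-filter smoothing, thresholded local maxima, sub-frame
parabolic peak refinement, and a 0.15 s refractory period (a 400 bpm
ceiling, beyond any plausible larval rate). `estimate_fH()` reproduces the
manual counting protocol: seven 15-s clips tiling the window from 0:30,
each count divided by 0.25 min and averaged. Seven clips leave the final
15 s of a 2.5-min recording unused even though eight would fit; the
counting protocol is specified as seven, so the package follows it and
notes the unused tail. `detect_arrhythmia()` operationalizes
"discontinuous spikes" as any inter-beat interval exceeding twice the
median interval — a deterministic stand-in for the visual verification
used in practice; with fewer than three beats the verdict is indeterminate
(`NA`), distinct from `FALSE`.

## Estimating T~AB~

`fit_two_segment()` fits the continuous two-segment linear model in
Arrhenius coordinates by exhaustive search: 200 candidate breakpoints are
placed between the 2nd and (n−1)th ordered x-values, exact least squares is
solved at each under the continuity constraint, and the global minimum is
returned. Exhaustive search with exact per-candidate solutions is cheap at
n ≤ 12 and removes the nondeterminism of iterative segmented-regression
estimators; the test-suite verifies exact agreement with an independent
brute-force fitter on a thousand random instances. Whether published
breakpoint fits constrain continuity between segments is usually left
unstated; continuity is the standard assumption in segmented regression and
is imposed here.

A breakpoint must earn its keep: `status = "no_breakpoint"` when the
two-segment SSE is not below 95% of the single-line SSE (configurable), or
when the slopes are effectively equal. Under heavy noise a small fraction
of individuals legitimately ends up without an identifiable breakpoint,
mirroring real datasets where T~AB~ cannot be computed for a few fish.

Tie-breaks and conventions in `compute_metrics()`: T~peak~ ties resolve to
the lower temperature (conservative for an upper-limit proxy); df~H~/dT
uses steps with T ≤ T~AB~ *inclusive* ("prior to the breakpoint" is
ambiguous about inclusivity); T~Arr~ is reported at step resolution — the
assay's observable — rather than interpolated.

## Population-level inference

Each index is modelled as `y ~ incubation + (1 | clutch)` by REML
(`lme4`/`lmerTest`), with marginal and conditional R² by the
variance-partition formulas, a boundary-corrected (halved χ²₁)
likelihood-ratio test for the clutch variance, and Tukey-adjusted pairwise
contrasts between incubation groups via estimated marginal means.

The proportion of individuals past an endpoint is modelled by logistic
regression on temperature, incubation and their interaction. Clutch enters
as a cluster-robust covariance correction on the fixed-effects fit rather
than a random intercept: in these curves the clutch variance component is
tiny (published marginal and conditional R² nearly coincide), and the
fixed-effects fit keeps the estimate deterministic and the inverse
prediction closed-form. This is a deliberate divergence from a
random-intercept GLMM. Complete separation is detected and resolved with a
small ridge penalty, flagged on the fit. Inverse prediction solves
logit(p) = a + s·T with delta-method standard errors — the classical LD50
construction — at p = 0.10, 0.50, 0.95. Both modes are exposed: the joint
interaction model evaluated at any incubation temperature, and per-group
temperature-only fits.

The T~AB~ distribution per group is summarized by a Gaussian kernel
density with the 0.9·min(sd, IQR/1.34)·n^(−1/5) rule-of-thumb bandwidth
(the default of the common plotting routines) on a 0.05 °C grid over the
data range ± 3 bandwidths. The overlay statistic

ΔN(T) = density of individuals at T~AB~ − fitted proportion past the
endpoint

is the package's group-level "optimal range" construction: its maximum and
the range within 90% of that maximum (tolerance configurable) mark where
the most individuals sit at their thermal-optimum proxy relative to those
already at an upper limit. Note the deliberate unit mismatch — a density
(per °C) minus a dimensionless proportion — reproduced literally because
that is how the statistic is defined and scaled in practice; treat ΔN as a
relative, not absolute, quantity.

ΔN sampled at the protocol steps is smoothed with a thin-plate regression
spline (`mgcv`, basis dimension k = 4 for the T~peak~ overlay and k = 9
for T~Arr~, smoothing parameter by GCV). The decline breakpoint is the
lowest 0.05 °C-grid temperature where the smooth's central-difference
first derivative turns negative and stays negative for at least 0.5 °C;
the persistence window suppresses noise-triggered sign flips, and a
numerical tolerance scaled to the data range keeps flat smooths from
producing spurious declines. With the small k the smooth can wiggle near
the left boundary and occasionally declares an early decline there;
breakpoints should be read alongside the plotted smooth.

```{r pipeline}
res <- run_pipeline(config = cfg)
subset(res$thresholds, endpoint == "T_Arr" & p_level == 0.50)
```

## Numerical and reproducibility choices

* Temperatures are °C everywhere; the Kelvin conversion (+273.15) exists
  only inside the Arrhenius transform.
* A seed is mandatory in every simulation config; reruns with the same
  config are byte-identical on disk, and every output file carries a
  header comment with the stage, seed and a config fingerprint.
* Degenerate inputs fail loudly: fewer than 5 points for a segmented fit,
  all-equal abscissae, identical values in a KDE, a single clutch in the
  mixed model (flagged ordinary-least-squares fallback), non-positive
  effective slope in inverse prediction.
* Test problem sizes were chosen to exercise the estimators at the study's
  scale where that matters (407 individuals for slope recovery; 500
  individuals for threshold-vs-quantile agreement; 1000 random instances
  for the breakpoint oracle; 100 replicate cohorts of 120 for the
  qualitative ordering check) while keeping the default suite fast.

## Known limitations

* The ΔN subtraction inherits the density-vs-proportion unit mismatch
  described above.
* Simulated fractions of arrhythmic individuals by the final step run
  higher than published ones: observed-group SEMs understate the latent
  T~Arr~ spread under right-censoring, and the calibration deliberately
  uses the published table values rather than inflating them.
* The rejection step conditions the marginal threshold distributions
  slightly; at the default SDs the effect is an order of magnitude below
  the between-group differences of interest.
* `detect_arrhythmia()` is a single-rule surrogate for visual
  verification; its gap factor should be tuned against a labelled sample
  before use on real traces.
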