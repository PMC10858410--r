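# cardiotherm

Simulation and analysis of stepwise cardiac thermal-performance assays in
larval fish, for thermal ecophysiologists who need per-individual cardiac
thermal indices and population-level thermal-limit inference from
heart-rate-versus-temperature profiles.

In these assays, anaesthetized larvae are warmed through a fixed series of
temperature steps (by default 9–25 °C in twelve steps: 2 °C increments to
19 °C, then 1 °C increments; 5 min hold + 2.5 min filming per step) while
heart rate f_H is measured at each step until cardiac arrhythmia. The
package covers the whole chain:

* **Synthetic populations** (`population_config()`, `generate_dataset()`)
  with clutch random intercepts, incubation-temperature fixed effects,
  individual variation and right-censored arrhythmia — calibrated to a
  published larval smelt assay (e.g. T_AB = 9.13 + 0.63 × incubation °C) —
  so every stage is testable without raw data.
* **Trace processing** (`synth_trace()`, `detect_beats()`,
  `estimate_fH()`, `detect_arrhythmia()`): beats-per-minute and arrhythmia
  flags from 1-D cardiac activity traces, mirroring the seven 15-s clip
  counting protocol (count / 0.25 min, averaged).
* **Per-individual indices** (`fit_two_segment()`, `compute_metrics()`,
  `extract_metrics()`): the Arrhenius breakpoint temperature T_AB —
  continuous two-segment least squares on log10 f_H vs 1000/K, global
  exhaustive-search minimum — plus T_peak, T_Arr (censoring-aware), f_H0,
  f_Hpeak, cardiac scope Δf_Hpeak−H0 and df_H/dT.
* **Population inference** (`fit_random_intercept_lmm()`,
  `pairwise_contrasts()`, `fit_reached_curve()`, `inverse_predict()`,
  `kde_tab()`, `delta_n_curve()`, `smooth_decline_breakpoint()`):
  random-intercept mixed models with marginal/conditional R², Tukey
  contrasts, logistic "proportion reached" curves with 10/50/95%
  inverse prediction (delta-method SEs), T_AB kernel densities, the
  ΔN(T) = density-at-T_AB − proportion-past-endpoint overlay statistic
  with its maximal range, and penalized-spline decline breakpoints.

`run_pipeline()` orchestrates simulate → extract → analyze → report; a thin
command-line front end lives at `inst/scripts/cardiotherm`. Methods,
assumptions and numerical choices are documented in
`vignettes/cardiac-thermal-performance.Rmd`.

## Worked example

```r
library(cardiotherm)

cfg <- population_config(n_per_group = c(30, 30, 30), seed = 42)
res <- run_pipeline(config = cfg)

aggregate(cbind(T_AB, T_peak, T_Arr) ~ incubation_C, res$metrics,
          function(x) round(mean(x, na.rm = TRUE), 1))
#>   incubation_C T_AB T_peak T_Arr
#> 1            9 15.7   17.3  20.6
#> 2           12 16.7   19.0  21.5
#> 3           15 18.4   20.5  23.0

round(res$lmm$T_AB$beta[, -1], 3)
#>   estimate    se     df      t p
#> 1   11.531 1.004 72.647 11.487 0
#> 2    0.453 0.077 81.058  5.856 0

subset(res$thresholds, p_level == 0.10)
#>  endpoint incubation_C p_level temperature        se
#>    T_peak            9     0.1    13.74169 0.3287512
#>    T_peak           12     0.1    16.15173 0.7433938
#>    T_peak           15     0.1    18.05660 0.7871323
#>     T_Arr            9     0.1    17.71864 0.6992227
#>     T_Arr           12     0.1    19.02869 0.7815214
#>     T_Arr           15     0.1    20.54869 0.8836098
```

The group means show the expected physiological ordering
T_AB < T_peak < T_Arr within every incubation group, and all three indices
rising with incubation temperature — warmer-incubated larvae shift their
thermal optimum proxy and upper limits upward. The mixed model recovers a
positive incubation slope for T_AB (0.45 ± 0.08 °C per °C of incubation in
this small cohort), and the 10% thresholds — the temperature at which 1 in
10 larvae has already peaked (T_peak) or gone arrhythmic (T_Arr) — likewise
increase with incubation.

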