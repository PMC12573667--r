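# gridsurv

Quadrat-based Poisson regression of clonogenic cell survival after
spatially fractionated (GRID) X-irradiation.

## The problem

GRID therapy delivers a deliberately heterogeneous dose pattern — high-dose
*peaks* separated by low-dose *valleys* — through a collimator array.
Assessing the resulting *local* biological effect in vitro is hard: survival
varies from millimetre to millimetre, and small regions contain few
colonies, so counts are Poisson-distributed and ordinary least-squares
dose–response fitting is inappropriate.

`gridsurv` implements a complete analysis pipeline for this setting, aimed
at radiobiologists running clonogenic assays under modulated fields:

1. **Dose maps** — synthetic striped/dotted/open GRID patterns with a
   Gaussian penumbra, or measured maps from radiochromic film via netOD
   calibration (`compute_netod()`, `fit_calibration()`, `netod_to_dose()`),
   with relative rescaling between nominal doses.
2. **Geometry** — peak-region segmentation at 95% of the maximum dose
   (`segment_peaks()`) and the exact Euclidean distance `d` (cm) from every
   pixel to the nearest peak rim (`distance_to_peak_rim()`).
3. **Quadrats** — co-registration of colony centroids with dose/distance
   maps and aggregation into 1 mm² quadrats: colony count `NC`, mean dose
   `D`, mean distance `d` (`partition_and_aggregate()`).
4. **Survival models** — Poisson generalized linear models with log link
   fitted by IRLS:

   - LQ:  `NC = NC0 · exp(−αD − βD²)`
   - MLQ: `NC = NC0 · exp(−αD − βD² − δDd)`

   The extra `δDd` term couples dose to distance-from-peak and acts as an
   empirical descriptor of spatially mediated (bystander-like) effects;
   `δ < 0` means valley cells fare better than local dose alone predicts.
5. **Model comparison** — repeated replicate-stratified 4-fold
   cross-validation with percentile confidence intervals for all
   parameters, AIC/BIC, RMSE/MAE (`repeat_cv()`), paired t-tests on
   predictions (`compare_models_ttest()`), and a selection report
   (`model_selection_report()`).

A first-class synthetic-data generator (`simulate_experiment()`,
`simulate_study_quadrats()`, `simulate_calibration_films()`) reproduces the
full study design — 3 patterns × 3 doses (2, 5, 10 Gy) × 4 replicates + 4
controls, 64 × 47 quadrats per flask — with colonies placed as an
inhomogeneous Poisson point process, so the whole pipeline is testable
without any measured data.

## Worked example

```r
library(gridsurv)

spec  <- grid_pattern_spec("striped")            # 5 mm open / 10 mm blocked
dmap  <- render_dose_map(make_pattern_mask(spec, spacing = 0.2), 5, spec,
                         spacing = 0.2)
peaks <- segment_peaks(dmap)                     # >= 95% of max dose
st    <- peak_valley_stats(dmap, peaks)
# peak 4.06 Gy, valley 0.91 Gy, PVDR 4.46

dist     <- distance_to_peak_rim(peaks)          # cm to nearest peak rim
params   <- list(nc0 = 2.4719, alpha = 0.2485, beta = 0.0321, delta = -0.0401)
colonies <- simulate_colonies(dmap, dist, params, seed = 7)   # 4262 colonies
tab      <- partition_and_aggregate(colonies, dmap, dist)     # 64 x 47 quadrats

study <- simulate_study_quadrats(experiment_config(params = params), seed = 7)
mlq   <- fit_survival_model(study, "MLQ")
mlq
#> Poisson GLM survival fit: MLQ model
#>   NC0 = 2.4526, alpha = 0.2343 /Gy, beta = 0.0343 /Gy^2, delta = -0.0220 /(Gy cm)
#>   n = 120320, logLik = -159575.04, AIC = 319158.09, BIC = 319196.88 (7 iterations)
```

The rendered striped field loses ~18% of the nominal dose in its peaks and
scatters ~22% of the peak dose into the valleys, matching measured EBT3
film dosimetry of this setup. The joint MLQ fit recovers the generating
parameters within sampling error; `delta` is the weakly identified one (its
single-fit standard error is ≈ 0.009), which is why recovery studies
average over replicate simulations. Comparing models on the same data:

```r
lq <- fit_survival_model(study, "LQ")
model_selection_report(lq, mlq)$table
#>   metric        LQ       MLQ     delta
#> 1 logLik -159578.1 -159575.0 -3.082665
#> 2    AIC  319162.3  319158.1  4.165329
#> 3    BIC  319191.3  319196.9 -5.532581
```

Positive deltas (LQ − MLQ) favour the MLQ model. See the methods vignette
(`vignettes/gridsurv-methods.Rmd`) for the model assumptions, parameter
defaults and numerical choices.

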