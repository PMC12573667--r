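---
title: "Methods: quadrat Poisson regression of GRID survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadrat Poisson regression of GRID survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridsurv)
```

## The statistical model

Clonogenic survival after irradiation is classically described by the
linear-quadratic (LQ) model: the surviving fraction at dose $D$ is
$\exp(-\alpha D - \beta D^2)$, with $\alpha$ (Gy$^{-1}$) the linear and
$\beta$ (Gy$^{-2}$) the quadratic cell-kill coefficient. In a GRID field
the dose varies over millimetres, so instead of one survival value per
flask we model the colony count $NC$ in each 1 mm$^2$ quadrat:

$$ NC \sim \mathrm{Poisson}(\lambda), \qquad
   \log \lambda = \lambda_0 - \alpha D - \beta D^2 \;(-\, \delta D d), $$

where $NC_0 = e^{\lambda_0}$ is the expected count at zero dose, $D$ the
quadrat-mean dose, and — in the modified LQ (MLQ) variant — $d$ the
quadrat-mean Euclidean distance (cm) from the nearest peak-region rim.
The $\delta D d$ interaction is an empirical descriptor of spatially
modulated effects such as bystander signalling from peak to valley cells:
it vanishes inside peaks ($d = 0$) and in open fields, and $\delta < 0$
corresponds to a pro-survival signal in the valleys. This is a Poisson
generalized linear model with log link, $\log \lambda = X\xi$, with LQ
design rows $[1, D, D^2]$ and MLQ rows $[1, D, D^2, Dd]$; the survival
parameters are sign-flipped regression coefficients, so fitted values are
directly comparable with conventionally reported $\alpha, \beta, \delta$.

Model assumptions worth stating explicitly:

* counts in distinct quadrats are independent given the covariates (no
  residual spatial correlation); `poisson_dispersion_test()` checks the
  Poisson mean–variance relation per condition;
* all quadrats share one area (1 mm$^2$), so no offset term is needed and
  $NC_0$ absorbs the area and the plating efficiency;
* the dose map and the colony frame are registered by translation only
  (fixed scanner fixture), handled in `register_to_common_frame()`.

## Fitting and inference

`fit_poisson_glm()` maximises the Poisson likelihood by iteratively
reweighted least squares (IRLS), initialised from the working response
$\log(\max(y, 0.5))$ and stopped when the relative log-likelihood change
falls below $10^{-10}$ (default cap 100 iterations), followed by one
polishing Newton step so the score equations $X^\top(y - \hat\mu) = 0$
hold to numerical zero (the packaged tests require $<10^{-8}$ and verify
agreement with both direct likelihood maximisation and `stats::glm`).
The covariance is the inverse Fisher information $(X^\top W X)^{-1}$,
$W = \mathrm{diag}(\hat\mu)$; `wald_inference()` reports z-based tests and
95% intervals on both the regression and the survival scale ($NC_0$ by
the delta method). AIC $= 2k - 2\ln L$ and BIC $= k\ln n - 2\ln L$.

Degenerate designs are handled explicitly: a rank-deficient design is an
error, except the one structural case — an MLQ fit on data whose $Dd$
column is identically zero (open fields and controls only). That column
carries no information, so the model is reduced to LQ and flagged
`reduced = TRUE` with $\delta =$ NA, rather than silently pseudo-inverted.

## Dose maps, geometry, and their parameters

`grid_pattern_spec()` describes the collimation: striped fields with 5 mm
open / 10 mm blocked periods, dotted fields with 5 mm holes at 18 mm
pitch, or open fields. Rendering maps the ideal binary transmission mask
through a Gaussian penumbra blur onto dose:

$$ D(x,y) = D_\mathrm{nom}\,\bigl[v + (t - v)\, G_\sigma * M(x,y)\bigr], $$

with peak transmission $t$, valley fraction $v$ and penumbra width
$\sigma$. The measurable quantities are the peak/valley plateau doses;
a two-level-plus-blur model is the minimal shape that reproduces them.
Defaults (all tunable): $\sigma = 0.8$ mm; striped $t/v = 0.82/0.18$ and
dotted $0.70/0.10$, chosen so a 5 Gy nominal delivery yields peak/valley
doses of about 4.1/0.9 Gy (striped) and 3.5/0.5 Gy (dotted), the levels
measured by film dosimetry for this irradiation setup. The valley plateau
width and penumbra slope are not constrained by those measurements; only
the plateau levels are calibrated.

Peak regions are segmented at $\ge 95\%$ of the reference maximum. The
reference maximum is robust — the 99.9th percentile of the map — so a
single noisy film pixel cannot shift the threshold; on noiseless synthetic
maps it equals the true maximum. It may also be supplied pooled per GRID
configuration. The distance map is an exact Euclidean distance transform
(via `EBImage::distmap`, verified against brute-force search in the
tests): $d = 0$ on peak pixels, else the distance in cm to the nearest
peak pixel. Distances are in centimetres because $\delta$ is conventionally
reported in Gy$^{-1}$cm$^{-1}$.

For peak/valley statistics the valley is defined operationally as pixels
at $\le 25\%$ of the reference maximum and $\ge 2$ mm from the peak rim,
which excludes the penumbra; PVDR = mean peak dose / mean valley dose,
computed per map by default (a pooled reference is available since the
per-film-vs-pooled convention is ambiguous in practice).

## Film dosimetry

netOD is the background-corrected log-ratio
$\log_{10}[(I_\mathrm{unexp}-I_\mathrm{bg})/(I_\mathrm{exp}-I_\mathrm{bg})]$,
with a single scalar background per scan (opaque-film reading). The
calibration model is the standard radiochromic-film form
$D = b\,\mathrm{netOD} + c\,\mathrm{netOD}^{\,n}$ with $n$ fitted: for
fixed $n$ the model is linear in $(b, c)$, so the fit profiles the linear
part with `lm.fit` and optimises the residual sum of squares over $n$
alone — robust, and exact to numerical tolerance on noiseless data. Noise
can push zero-dose netOD slightly negative; the power term is evaluated
on the non-negative part so fractional exponents stay real. Three channel
curves are fitted; the channel with the highest $R^2$ (ties by lowest
RMSE) is selected — red, for EBT3. At prediction time netOD outside the
calibration range is clipped with a warning rather than extrapolated, and
negative dose predictions are clipped to zero. GRID maps are measured at
one nominal dose (5 Gy) and rescaled exactly to 2 and 10 Gy, which
preserves the PVDR and every dose ratio.

## The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
at the study's own design: 3 patterns $\times$ 3 nominal doses (2, 5,
10 Gy) $\times$ 4 replicates + 4 unirradiated controls = 40 flasks, each
a 64 $\times$ 47 mm region tiled by 1 mm$^2$ quadrats (3008 per flask,
120 320 in total). Two levels are provided:

* `simulate_colonies()` / `simulate_experiment()` place individual
  colonies as an inhomogeneous Poisson point process with pixel-level
  intensity $(NC_0/A)\exp(-\alpha D - \beta D^2 - \delta D d)$, sampled
  by thinning a homogeneous process at the maximum intensity (exact for
  any bounded intensity). A master seed is split into per-flask streams.
* `simulate_study_quadrats()` draws counts directly per quadrat at the
  quadrat-mean covariates. This is the generator used for
  parameter-recovery studies: because generation and fitting use the same
  covariates, the fit is exactly unbiased for the generating parameters,
  whereas point-level generation adds a small within-quadrat Jensen bias
  that is a property of aggregation, not of the fitter.

Default generating parameters are the fitted study values
($NC_0 = 2.448$, $\alpha = 0.2539$, $\beta = 0.0388$, $\delta = 0$;
alternative sets for MLQ and open-field studies are passed explicitly).
Maps are rendered at 0.2 mm/px (25 pixels per quadrat), which preserves
quadrat-mean covariates to well within all recovery tolerances; pattern
geometry tests use 0.05–0.1 mm.

What the generator does **not** emulate: scanner optics and film grain,
film-lot aging, colony merging/undercounting at high density, edge
effects at the flask walls, cell-cycle or repair kinetics, and any
mechanistic diffusion model of bystander signalling. Passing tests
therefore demonstrate that the *pipeline* recovers the parameters of its
own generating model at study scale — not that the MLQ model is the
correct biology for any particular cell line.

## Cross-validation and model comparison

`assign_folds()` splits by **flask**, not by quadrat: quadrats within a
flask share dose geometry and would leak spatial structure across a
quadrat-level split. The replicate-stratified default places one
replicate of every condition in each of $k = 4$ folds (75% training /
25% testing); a free-permutation strategy is available. `repeat_cv()`
repeats the procedure with independent seeded fold assignments and
summarises parameters, AIC, BIC and count-scale test RMSE/MAE by their
mean and percentile (2.5/97.5%) interval over pooled repeat $\times$ fold
values. The packaged default is 100 repeats (the published analysis used
4000; repeats only tighten the percentile intervals, and the
model-selection checks in this package use 200 repeats at study scale,
about 2.5 minutes on one CPU). `compare_models_ttest()` uses paired
two-tailed t-tests within each nominal-dose group, since both models
predict the same quadrats; a Welch unpaired variant is provided.

## Numerical choices and recovery-study design

Two identifiability facts shape the recovery studies. At study scale the
Fisher standard error of $\hat\alpha$ in the joint LQ fit is $\approx
0.005$ (about 2% of $\alpha$), and that of $\hat\delta$ in the joint MLQ
fit is $\approx 0.009$ — roughly 22% of $|\delta| = 0.0401$. The $\delta$
term is weakly identified by design: it is informed only by
within-valley variation of $d$ at nearly constant $D$, and its column is
correlated with $D$ and $D^2$. A single simulated study therefore cannot
pin $\delta$ tightly. The package's recovery checks and
`scripts/acceptance.R` consequently report the **mean maximum-likelihood
estimate over independent replicate simulations** of the full design (40
replicates for LQ and open-field studies, 100 for MLQ), which makes the
Monte Carlo error of the report small relative to each parameter's
sampling spread; the sign-stability check for $\delta$ uses 20
single-fit replicates. These replicate counts are fixed design choices of
the recovery study, not tuning knobs.

Other numerical choices: quadrat cells are half-open $[x, x+s) \times
[y, y+s)$ so every centroid maps to exactly one quadrat; quadrat
covariates are means over the pixels whose centres fall in the cell;
peak-threshold comparison is inclusive ($\ge$); the degenerate paired
t-test (zero-variance difference) is reported as $p = 1$ with a flag,
using a relative tolerance of $10^{-9}$ because a constant offset never
yields an exactly zero floating-point variance.

## Known limitations

* Registration is translation-only; rotation or deformation between the
  colony scan and the film scan is not estimated.
* The valley definition (≤ 25% of max, ≥ 2 mm from the rim) is one
  reasonable operationalisation; PVDR values shift slightly under others.
* $\delta$ conflates genuine intercellular signalling with dose-rate and
  repair effects that also differ between peaks and valleys; nothing in
  the fit can separate them.
* The Poisson assumption is checked, not enforced; overdispersed data
  (e.g. clustered colony formation) would need a negative-binomial
  extension, which is out of scope.
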