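---
title: "Quantifying balance alteration from center-of-pressure sway: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying balance alteration from center-of-pressure sway: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copbalance)
```

## The problem

Postural sway — the continuous small movement of the body's center of
pressure (CoP) during quiet standing — carries diagnostic information about
balance control in older adults. A force platform records the CoP as a
two-channel displacement time series (antero-posterior, AP, and
medio-lateral, ML, in mm), typically one minute per eye condition (open,
OE; closed, CE) at 50 Hz. From each recording a standard battery of sway
indexes is computed; individual indexes are then screened as markers of a
clinically defined *balance alteration* (inability to hold feet-together,
semi-tandem, or tandem stance for 10 s, or one-legged stance for 5 s), the
best marker is dichotomized at a ROC-optimal cut-off, and an adjusted
logistic model converts the dichotomized marker plus demographics into an
individual risk probability.

`copbalance` implements this pipeline end to end: sway-index extraction,
group comparison and ROC/AUC screening, Youden cut-off selection, the
adjusted logistic risk model with Hosmer–Lemeshow calibration, Cochran
sample-size planning — and a synthetic cohort generator so that every stage
is exercised without access to clinical data.

## The sway index set

Each recording is mean-centred per channel (making all indexes invariant to
where the subject stood on the platform) and summarized by 39 measures per
eye condition, named `BASE + DIRECTION (AP|ML|RD|planar) + CONDITION
(OE|CE)`; `cop_metric_registry()` is the machine-readable roster. With
$RD_i = \sqrt{AP_i^2 + ML_i^2}$ and $T = (n-1)/f_s$:

* **Distance** (15): mean distance `MDIST*` ($\overline{RD}$,
  $\overline{|d|}$), RMS distance `RDIST*`, range `RANGE*` (the planar
  range is the diameter of the sampled statokinesiogram, computed exactly
  on its convex hull), total excursion `TOTEX*` (path length) and mean
  velocity `MVEL*` $= TOTEX/T$.
* **Area** (3): 95% confidence circle
  $\pi\,(MDIST + 1.645\,s_{RD})^2$; 95% confidence ellipse
  $2\pi F \sqrt{s^2_{AP}s^2_{ML} - s^2_{AP,ML}}$ with the large-sample
  constant $F = 3.00$ (exact quantiles available by flag); sway area
  `AREASW` $= \frac{1}{2T}\sum_i |AP_{i+1}ML_i - AP_iML_{i+1}|$, the rate
  at which the trajectory sweeps area around its mean.
* **Hybrid** (6): `MFREQ` $= MVEL/(2\pi\,MDIST)$ (the rotation frequency of
  an equivalent circular sway) and its per-axis analogues
  $MVEL_d/(4\sqrt{2}\,MDIST_d)$; three fractal dimensions
  $\log n / \log(n\,d/TOTEX)$ with characteristic diameter $d$ set to the
  planar range, the confidence-circle diameter, or the area-equivalent
  diameter of the confidence ellipse.
* **Frequency** (15): for each of AP, ML, RD, the one-sided PSD is
  estimated by Welch's method and summarized over the 0.15–5 Hz
  posturographic band through spectral moments
  $\mu_k = \sum f^k G(f)\,\Delta f$: total power `POWER` ($\mu_0$), the 50%
  and 95% power frequencies, centroidal frequency $\sqrt{\mu_2/\mu_0}$, and
  frequency dispersion $\sqrt{1 - \mu_1^2/(\mu_0\mu_2)}$.

The classical battery this follows names only a subset in print and defers
the full roster to supplementary material; the registry completes the count
to 39 with total excursion and the fractal dimensions, which belong to the
same classical family, and isolates the roster so it can be corrected
without touching code.

### Numerical choices

* **PSD estimator.** Welch with Hann window, 10 s segments, 50% overlap,
  linear detrend per segment — a standard low-variance choice for 60 s
  records. Records shorter than one segment fall back to a single segment
  with a warning. The density normalization integrates to the signal
  variance (a sinusoid of amplitude $A$ integrates to $A^2/2$). Whether a
  real device detrends or only mean-centres before spectral analysis is
  generally unspecified; both are offered (`detrend` argument).
* **Degenerate inputs.** Every ratio-type measure (`MFREQ*`, `CFREQ*`,
  `FREQD*`, fractal dimensions, the power quantiles of a zero-power
  series) is defined as 0 when its denominator vanishes, with a warning —
  a constant trace yields an all-zero, all-finite metric vector rather
  than NaNs that would poison cohort statistics.
* **Duration convention.** $T = (n-1)/f_s$ counts inter-sample spans, so
  the mean velocity of a two-point record is finite.
* **Planar range.** Exact maximum pairwise distance via the convex hull
  ($O(n\log n)$); the $O(n^2)$ scan is kept as a test oracle.

## ROC screening and the Youden cut-off

`roc_curve()` uses the inclusive, higher-is-riskier convention (positive
when score ≥ threshold; thresholds at midpoints between distinct scores
plus $\pm\infty$ sentinels) and the trapezoid AUC, which on these
thresholds equals the Mann–Whitney pair-counting statistic with ties
counted ½ — an identity the test suite checks exactly on random instances.
Confidence intervals use DeLong's variance estimate (Hanley–McNeil by
flag); an anti-predictive marker (AUC < 0.5) triggers a warning rather
than silent auto-flipping. `youden_cutoff()` maximizes
$J = \text{sens} + \text{spec} - 1$, breaking ties toward the lowest
(most sensitive) cut-off; dichotomization is inclusive at the boundary.

## The adjusted risk model

`fit_logistic()` is maximum likelihood via IRLS (`stats::glm`,
binomial family, tolerance $10^{-10}$, 50 iterations), complete-case on
the model variables with a logged drop count, with Wald standard errors,
p-values and odds-ratio intervals ($OR = e^\beta$ exactly; Wald matches
the symmetric-on-log-scale appearance of published OR intervals).
Perfect separation and rank deficiency abort with informative errors.
The individual risk follows the logistic equation

$$P = \frac{1}{1 + e^{-(\beta_0 + \beta_1 X_1 + \beta_2 X_2 + \beta_3 X_3 + \beta_4 X_4)}}$$

with $X_1$ the dichotomized AP mean velocity, $X_2$ sex coded woman = 1,
$X_3$ age (years), $X_4$ BMI (kg/m²). Calibration uses the
Hosmer–Lemeshow test: subjects ranked by fitted probability, ten
equal-count risk groups (quantile breaks; ties stay together, so fewer
groups can form), $\chi^2$ over both outcomes, df = groups − 2. Sample-size
planning uses Cochran's large-population formula $n = z^2 p q / d^2$,
rounded up.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws, per subject: age, BMI, gait speed (stored in
cm/s; the plausible unit for its reference values) and squat count from
per-group truncated normals; sex at an identical 72.2% women in both
groups; multimorbidity, polypharmacy and prior-falls flags at per-group
rates; and four velocity targets (AP/ML × OE/CE) that parameterize the
trajectory simulator. Velocity targets are moment-matched lognormals
(velocities are positive and right-skewed; a truncated-normal option is
kept for analytic checks) tied together by a latent sway-severity Gaussian
copula (loading 0.8): a subject's sway magnitudes are correlated across
axes and eye conditions, and this correlation also keeps the open-eyes AP
velocity the designed best-discriminating index, matching the reference
ordering in which every closed-eyes index ranks below the top open-eyes
ones. With the default configuration the implied AUC of the AP open-eyes
velocity is 0.710 and its implied optimal (density-crossing) cut-off is
12.45 mm/s.

Two endpoint modes: **A** (default) fixes group membership by sampling, so
group sizes and per-group distributions match the printed tables exactly
in expectation; **B** draws the endpoint from the generating logistic
model given the covariates, which is what parameter-recovery and
calibration experiments need.

`generate_trajectory()` simulates band-limited sway: Gaussian displacement
increments low-pass filtered below 5 Hz (zero-phase Butterworth), then
rescaled so the computed axis mean velocity equals its target *exactly* —
the rescaling is exact for this one metric, everything else is emergent.
No quantization is applied, so the round-trip is machine-precision.

Deliberate non-goals: no inverted-pendulum biomechanics, no
between-covariate correlations (age and BMI are independent within group),
no device-level artifacts (drift, quantization, load-cell noise). Passing
tests therefore demonstrate that the *statistical machinery* behaves
correctly under the study's printed distributional structure — not that
the generator reproduces every feature of clinical sway data. Quantities
that depend on the full joint distribution of the real data (the exact
published cut-off of 14.24 mm/s, the exact count of significant indexes)
are not desk-reproducible and are deliberately not asserted.

## Problem sizes used in the checks

The test suite exercises: full 414-subject studies (both endpoint modes);
parameter recovery at n = 50 000 (each generating coefficient within 3 SE);
Hosmer–Lemeshow type-I calibration over 1000 simulated cohorts of n = 1000
(rejection rate 5% ± 2%); DeLong coverage over 500 replicates; 1000
two-group replicates for the screening-AUC recovery; and exhaustive Youden
maximality on inputs up to n = 50. These sizes were chosen so each check's
Monte-Carlo error is well inside the asserted band.

## Known limitations

* The metric roster beyond the printed subset is a documented
  reconstruction; the registry isolates it.
* Raw p-values are reported in the screen (matching the screening
  convention of reporting unadjusted comparisons); Benjamini–Hochberg is
  available as a clearly labelled extension column.
* Wald inference only for the logistic model (no profile likelihood), and
  apparent (in-sample) AUC without optimism correction — matching the
  reference analysis rather than extending it.
* The Hosmer–Lemeshow mapping $\chi^2 = 7.147$, df = 8 → p = 0.521 is the
  one the implementation validates; published sources occasionally print
  inconsistent companion p-values for this statistic.
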