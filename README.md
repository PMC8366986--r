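# copbalance

Quantifying balance alterations in older adults from center-of-pressure
(CoP) sway recordings.

Standing balance is commonly assessed by recording the CoP trajectory on a
force platform — two displacement channels (antero-posterior AP and
medio-lateral ML, mm) sampled at 50 Hz for one minute per eye condition —
and summarizing it with a battery of stabilometric indexes. `copbalance`
implements the complete screening-and-risk-modelling analysis built on that
battery, for biostatisticians and movement scientists working with
posturographic data:

1. **Sway metrics** — the 39-index set per eye condition (78 per subject):
   distance measures (mean/RMS distance, range, total excursion, mean
   velocity `MVEL* = path length / T`), sway areas (95% confidence circle
   and ellipse, sway area per unit time), hybrid measures
   (`MFREQ = MVEL/(2π·MDIST)`, fractal dimensions) and Welch-PSD spectral
   measures on the 0.15–5 Hz band (total power, 50%/95% power frequencies,
   centroidal frequency `√(μ₂/μ₀)`, frequency dispersion).
2. **Cohort statistics** — mean ± SD / n (%) descriptives with t,
   Mann–Whitney or χ² (no continuity correction) group comparisons.
3. **ROC screening** — trapezoid AUC (exactly the Mann–Whitney
   pair-counting statistic) with DeLong confidence intervals,
   Youden-optimal cut-off `J = sens + spec − 1` (ties toward the most
   sensitive threshold, inclusive dichotomization), confusion statistics.
4. **Risk model** — adjusted logistic regression
   `P = 1 / (1 + exp(−(β₀ + β₁·velocity≥cutoff + β₂·sex + β₃·age + β₄·BMI)))`
   with Wald odds-ratio intervals, Hosmer–Lemeshow calibration (df = g − 2)
   and model AUC; Cochran sample-size planning `n = z²pq/d²`.
5. **Synthetic study generator** — cohorts with the published group
   structure (n = 414, 115 with / 299 without a balance alteration) and
   band-limited sway trajectories whose AP/ML mean velocities hit commanded
   targets exactly, so the whole pipeline runs end to end without clinical
   data.

## Worked example

The numbered scripts under `analysis/` run the whole study replica
(synthetic recordings → metrics → descriptives → index screen → risk
model); the same computation is available in one call:

```r
library(copbalance)
report <- run_balance_study(generator_config(seed = 1))
print(report)
```

Running the staged scripts prints, at the screening stage
(`analysis/04_screen_indexes.R`):

```
Indexes with a group difference at p < 0.05: 42 of 78
Top 10 by AUC:
     index  p_value   auc auc_lo auc_hi
  MVELAPOE 2.55e-12 0.722  0.665  0.779
 TOTEXAPOE 2.55e-12 0.722  0.665  0.779
 POWERAPOE 9.17e-12 0.716  0.659  0.773
 ...
```

The AP mean velocity with open eyes (`MVELAPOE`) ranks first — the
generator plants the group difference there, and total excursion ties it
exactly because the two are proportional. The model stage
(`analysis/05_risk_model.R`) then prints:

```
<cop_cutoff> cutoff = 11.05 (J = 0.359)
  sens 0.713  spec 0.645  ppv 0.436  npv 0.854  (tp 82 fp 106 tn 193 fn 33)
Logistic risk model (n = 414)
  term               OR   beta        p   95% CI
  constant         0.00 -21.77   <0.001   0.00-0.00
  mvelap_dic       4.43   1.49   <0.001   2.55-7.70
  sex_woman        0.65  -0.44    0.145   0.36-1.16
  age              1.25   0.23   <0.001   1.19-1.33
  bmi              1.15   0.14   <0.001   1.08-1.23
  Hosmer-Lemeshow chi2 = 9.647, df = 8, p = 0.291
  Area under ROC curve: 0.852
Cochran sample size: n = 369.98 -> 370 (z = 1.960, p = 0.404, d = 0.05)
```

Reading: on this synthetic cohort the Youden-optimal cut-off for the best
index is 11.05 mm/s (near the generator's density-crossing optimum of
12.45 mm/s); subjects at or above it have 4.4 times the odds of a balance
alteration after adjusting for sex, age and BMI; each additional year of
age multiplies the odds by 1.25; the calibration test does not reject
(p = 0.29); and the adjusted model discriminates better (AUC 0.852) than
the raw index alone (0.722). The individual risk for any profile comes
from `predict_probability()` — e.g. published external coefficients can be
applied directly:

```r
predict_probability(c(-17.32, 1.08, 0.23, 0.16, 0.16),
                    mvelap_dic = 0, sex_woman = 0, age = 70, bmi = 22.70)
#> [1] 0.07670372
```

i.e. a 7.7% probability of a balance alteration for a 70-year-old man with
BMI 22.70 whose AP mean velocity is below the cut-off.

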