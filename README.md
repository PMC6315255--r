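# funcprofile

Infer physical function from free-living wearable activity-monitor data.

Hip-worn accelerometers summarize movement as **activity counts per
minute**. Clinical capacity tests — the 400-m walk time (400MWT), 20-m walk
pace (20MPACE), five-repetition sit-stand rate (5CSPACE) — summarize what a
patient can do under supervision. `funcprofile` connects the two for
cohorts such as knee-osteoarthritis accelerometer studies. The pipeline:

1. **Wear time** — flag nonwear (runs of zero counts spanning > 90 min,
   allowing interruptions of ≤ 2 consecutive minutes with < 100 counts) and
   keep days with ≥ 10 h of wear.
2. **Segmentation** — partition each wear bout into homogeneous segments by
   divisive energy-statistic change-point analysis: the split maximizing
   the two-sample energy divergence
   `(|x||y|/(|x|+|y|)) (2E|X−Y| − E|X−X′| − E|Y−Y′|)`
   is accepted on a seeded permutation test, recursively.
3. **Function profile** — index each segment by its (mean, SD), partition
   that plane into equal-width pattern classes `[m1, m2) × [s1, s2)`, and
   form per subject the vector `a_l = (1/K) Σ_k t_lk` of average daily
   minutes per class over the K valid days.
4. **Ordinal model** — classify subjects into quartile bands (1 < 2 < 3)
   of each capacity measure with a weighted cumulative-logit additive
   model `P(Y ≤ c | X) = logit⁻¹(θ_c − α − Σ f_p(X_p))` over BMI, age, sex,
   height, OA subcohort and the profile (penalized spline smooths via
   mgcv's ordered-categorical family; inverse-prevalence weights).
5. **Evaluation** — held-out Goodman-Kruskal Gamma `(C − D)/(C + D)`,
   with/without the profile, and repeated stratified 5-fold
   cross-validation to tune the pattern-class interval width.

Because the motivating cohort data are access-restricted, the package
includes a synthetic cohort generator (`simulate_cohort()`) with a latent
per-subject function score driving both the activity-class mix and the
capacity measures, so the whole pipeline is exercised end-to-end without
any download.

## Worked example

```r
library(funcprofile)

report <- run_pipeline(pipeline_config(
  preset = "default", n_subjects = 150, days = 7,
  measure = "walk400", width = 700, seed = 1))
```

```
[funcprofile] simulating cohort: preset 'default', n = 150, 7 days
[funcprofile] subjects in: 150; with >= 1 valid day: 150; excluded: 0
[funcprofile] segments produced: 11665 over 1049 valid days
[funcprofile] held-out Gamma with profile 0.921, without 0.218 (delta +0.703)
```

The held-out Gamma with the profile is high because synthetic capacity is
driven by the same latent score that shapes the activity mix; the
covariates-only baseline fluctuates around zero because synthetic
covariates are drawn independently of that score (on real data both would
be positive and closer together). Individual stages are plain functions — see
`?detect_nonwear`, `?segment_bout`, `?build_grid`, `?function_profiles`,
`?fit_ordinal_gam`, `?holdout_evaluate`, `?cv_tune_width` — and the methods
vignette (`vignettes/function-profiles.Rmd`) documents the model,
parameter choices and limitations.

A quick tail-probability sanity check on a pattern class, with midinterval
values as μ and σ:

```r
chebyshev_bounds(c(2800, 3500), c(0, 700), k = 1.8)
#> $lower
#> [1] 2520
#> $upper
#> [1] 3780
#> $prob_lower_bound
#> [1] 0.691358
```

i.e. at least ~70% of that class's counts per minute lie between 2520 and
3780 — the lower moderate-intensity range.

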