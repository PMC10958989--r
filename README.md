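# demtrend

Estimating calendar-time trends in dementia incidence from ageing-panel data,
and projecting the future dementia burden, when the naive analysis is biased
by deaths between survey waves.

## The problem

Longitudinal ageing studies observe dementia status only at survey waves
(typically every two years), while deaths are known exactly from register
linkage. A participant who develops dementia and dies before the next wave is
never recorded as a case, so wave-to-wave ("subcohort") incidence rates are
biased downward — and if mortality trends change over the study period, the
*trend* in incidence is distorted too. `demtrend` implements both the naive
and the bias-corrected estimators so the contrast is explicit:

* **Algorithmic case definition** (`ascertain_dementia`): cognitive
  impairment (≥2 cognitive domains at or below 1.5 SD under the
  education-stratified reference mean, with a transient-decline reversal
  rule and an informant IQCODE path for proxy interviews) *and* functional
  impairment (≥1 ADL dependency), *or* a reported doctor's diagnosis.
* **Subcohort incidence** (`build_subcohorts`, `crude_rate`,
  `standardised_rate`): overlapping 4-year dementia-free subcohorts, with
  midpoint-imputed onset dates and direct age–sex standardisation.
* **Cox trend model** (`fit_cox_trend`): pooled-subcohort proportional
  hazards with age, age², sex, age×sex and a restricted cubic spline in
  calendar time; cluster-robust sandwich variance.
* **Three-state hidden Markov model** (`fit_msm`): the bias-corrected
  estimator. A continuous-time illness–death process (no dementia →
  dementia → death, no dementia → death) observed at waves with exact death
  dates and a misclassification (emission) layer. For each transition
  \(r \to s\),

  \(q_{rs}(t) = \exp\{\alpha_{rs} + \beta_{rs}^\top x(t)\}\),

  with age, sex and calendar time as covariates; the calendar effect on the
  onset intensity (linear, linear-spline, or restricted cubic spline) is the
  estimand. Interval probabilities use the closed-form matrix exponential of
  the progressive intensity matrix; a death at time \(t_d\) contributes
  \(\sum_s f_s(t_d^-)\, q_{s,\mathrm{dead}}\) over the unknown living state.
* **Burden projection** (`build_transition_array`, `run_projection`): a
  ten-state Markov cohort model (CVD × cognitive impairment × functional
  impairment, plus CVD and non-CVD death) propagated annually to 2040 under
  incidence scenarios (e.g. a 2.8%/yr rise vs a 2.7%/yr decline after 2018)
  and mortality-forecast variants, including a two-dimensional P-spline
  Poisson smoother over age × year (`fit_pspline_mortality`).
* **Synthetic cohort generator** (`simulate_panel`): a seeded ageing panel
  with the latent three-state process, refreshment samples,
  state-dependent measurements and linked deaths, so every estimator can be
  scored against its generating truth.

## Worked example

```r
library(demtrend)

cfg    <- cohort_config(n_core = 6000, seed = 7)  # V-shaped trend by default
panel  <- simulate_panel(cfg)
panel
#> Synthetic ageing panel: 9000 participants, 57702 person-wave rows, 2369 linked deaths
#> Waves: 1 2 3 4 5 6 7 8 9  dates 2002.5 - 2018.5

status <- ascertain_dementia(panel)
records <- build_subcohorts(panel, status)
round(sapply(split(records, records$subcohort), crude_rate), 1)
#>    1    2    3    4    5    6    7
#>  8.5  8.6  8.6  9.6 12.7 14.3 16.2     # per 1000 person-years

cox <- fit_cox_trend(records)
round(hr_curve(cox, c(2006, 2010, 2014), ref_year = 2002), 2)
#>   year   hr   lo   hi
#> 1 2006 0.71 0.50 1.02
#> 2 2010 0.73 0.53 0.99
#> 3 2014 0.86 0.65 1.15

fit <- fit_msm(panel, status, msm_spec(calendar = "piecewise",
                                       emission = "both"))
round(irr_curve(fit, c(2008, 2016), ref = 2002), 2)
#>   year  irr   lo   hi
#> 1 2008 0.69 0.54 0.90
#> 2 2016 1.08 0.87 1.33

round(annualise_irr(1.25, 2008, 2016), 1)
#> [1] 2.8
```

The generator's default onset intensity declines 5%/yr to 2008 and rises
2.8%/yr afterwards. The multistate fit recovers the decline (IRR 0.69 for
2008 vs 2002, 95% CI 0.54–0.90) and the subsequent rebound; the Cox curve
shows the same V-shape direction but, being blind to cases lost to death
between waves, with a damped contrast. `subgroup_trend_test()` adds
calendar-by-subgroup interactions (age, sex, education) with likelihood-ratio
tests, and `project_scenario()` carries a fitted trend into the ten-state
burden projection.

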