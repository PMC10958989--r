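---
title: "Bias-corrected dementia incidence trends and burden projection: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-corrected dementia incidence trends and burden projection: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `demtrend`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate. It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## 1. The estimation problem

Ageing panels observe dementia status only at survey waves (about every two
years here), while linked register deaths are dated exactly. Someone who
develops dementia after a wave and dies before the next is never observed as
a case. Wave-to-wave incidence analyses therefore undercount onsets, and the
size of the undercount depends on post-onset mortality — so calendar-time
*trends* from naive analyses are contaminated whenever mortality itself
trends. The package implements the naive estimator (overlapping 4-year
subcohorts) and the corrected one (a three-state hidden Markov model with
exact death times) side by side; their contrast on synthetic data with
elevated post-onset mortality is itself a tested deliverable.

Cumulative-incidence machinery for competing risks (Fine–Gray style) is
deliberately *not* used: the estimand is the instantaneous onset intensity
among living, dementia-free people, and treating death as a competing
"cure" would answer a different question.

## 2. Case definition

Dementia at a wave = (cognitive impairment AND functional impairment) OR a
reported doctor's diagnosis. The components:

* **Cognitive impairment**: scores in ≥ `min_impaired_domains` (default 2)
  cognitive domains at or below `mean − sd_multiplier × SD` (default 1.5)
  of the reference population — person-waves aged 50–80 with the same
  education level, pooled over waves. Pooling (rather than per-wave
  thresholds) is the default because it is stable at moderate sample sizes;
  a designated reference table can be supplied instead.
* **Transient decline**: a cognitive flag is rescinded when the consecutive
  wave improves by ≥ `improvement_sd` (default 1) reference SDs,
  operationalised as the *mean standardised change across the domains that
  were impaired* — the aggregation is not pinned down by the clinical rule,
  and the mean over impaired domains is the least arbitrary choice. Flags
  from proxy interviews and at a person's last observed wave cannot be
  rescinded.
* **Proxy path**: when domain tests are missing, an informant score
  strictly above `proxy_cutoff = 3.6` flags impairment (strict inequality
  deliberately).
* **Functional impairment**: ≥ `min_adl` (default 1) ADL dependencies.
* **Doctor diagnosis**: treated as absorbing (a report persists), with a
  config switch; an algorithmic-only variant drops this path entirely for
  sensitivity analyses, and the algorithmic case set is provably a subset
  of the default one.

Ascertainment is absorbing (first flagged wave defines onset for the
subcohort analysis); raw wave-level flags may revert, and those reversals
are exactly what the multistate model's misclassification layer absorbs.

## 3. Subcohort incidence

Each eligible baseline wave opens a subcohort of people aged 50+ and
dementia-free at baseline, followed to dementia, death, or 4 years. Onset
dates are imputed at the midpoint between the first-flagged wave and the
person's previous observed wave using actual interview dates (not nominal
wave years), which keeps person-years accurate. Priority on ties is
dementia < death < censoring. A death between waves with no intervening
dementia observation counts as a death — deliberately, since this is the
bias under study. Direct standardisation uses 5-year age bands by sex
against a census-shaped synthetic standard table (any table with the same
layout drops in); empty positively-weighted strata are dropped with
renormalisation and a warning.

## 4. Cox calendar-trend model

The pooled-subcohort Cox model uses follow-up time within subcohort as the
time scale and covariates age, age², sex, age×sex, plus a restricted cubic
spline in calendar year. The spline has internal knots at 2006 and 2010;
boundary knots default to 2002 and 2016 so the basis spans the subcohort
baselines (the boundary placement is a package choice — only the internal
knots are scientifically motivated, and the restricted basis is linear
beyond the boundaries anyway). Calendar time is updated continuously along
follow-up by splitting records into 0.5-year episodes (baseline-fixed
calendar is available as a switch). Ties default to Breslow — simplest to
verify against a hand-coded partial likelihood, with Efron available and
identical when no ties exist. Variance is the cluster-robust sandwich on
person id, because people contribute to several overlapping subcohorts.
The proportional-hazards check augments the model with a follow-up-time ×
calendar-year interaction and reports a robust Wald test.

Estimation is delegated to `survival::coxph`; the package owns the design
construction, the spline basis (Harrell form, hand-coded and tested against
a constrained truncated-power oracle), the trend curve with delta-method
intervals, and the PH check.

## 5. The three-state hidden Markov model

States: 0 no dementia, 1 dementia, 2 dead; transitions 0→1, 0→2, 1→2, no
recovery. Each intensity is log-linear in covariates; on the onset
intensity, age enters linearly or as a restricted cubic spline (knots 60,
70, 80 by default), sex and optionally age×sex, and calendar time as the
estimand in one of three forms: linear, a linear spline with a break at
2008 (two slopes — the form that matches the generator's piecewise trend),
or a restricted cubic spline with knots 2002/2006/2010/2016 (mirroring the
Cox knots). Mortality intensities get linear age, sex, and optionally a
linear calendar term; splines on the mortality transitions added little at
the sample sizes the package targets and are omitted for parsimony.

**Likelihood.** Covariates are piecewise-constant per inter-wave interval.
Interval transition probabilities use the closed form of the progressive
3×3 matrix exponential, with the removable singularity at
`q12 = q01 + q02` handled by a series expansion (validated against
`Matrix::expm` and against Monte-Carlo trajectory frequencies). The forward
recursion runs over the two living states, scaled each step to avoid
underflow, and is vectorised across subjects (intervals grouped by
within-subject index), which is what makes replicate-level simulation
studies affordable in pure R. A death at `t_d` terminates the recursion
with `f0·(P00 q02 + P01 q12) + f1·P11 q12` over the unknown living state.
The initial distribution is a point mass at the observed entry state
(entrants are screened, and estimating initial misclassification from these
data adds little); emission probabilities
`e01 = P(observe dementia | none)` and `e10 = P(observe none | dementia)`
are estimated on the logit scale, both freed by default, with death
observed without error.

**Covariate timing.** Intervals are evaluated at their start by default
(age and calendar at the last wave), with a midpoint option. The start
convention is standard for panel data but carries an O(Δt) discretisation
error against a continuously varying truth; the package's own simulation
studies (coverage of the calendar slopes) use the midpoint option, which
removes most of that error at biennial spacing.

**Optimisation.** BFGS from crude-rate starting values (log observed
transition counts over person-years), followed by a single restart from the
optimum — the restart costs little and repairs occasional premature stops,
in particular when emissions head for the boundary. Multi-start with seeded
jitter is available (`n_starts`) but is not the default: with crude-rate
starts the likelihood has shown no local-optimum issues in the package's
simulation studies, and single-start keeps replicate studies affordable.
Standard errors come from the numerically differentiated observed
information; a non-positive-definite Hessian triggers a warning and
pseudo-inverse intervals. When emissions are truly absent the freed fit
sits on the open boundary (logit → −∞); its log-likelihood can rest a hair
(order N·ε) below the constrained fit's, which the tests treat as the
numerical identity it is.

**Inference.** `irr_curve` reports `exp(f(y) − f(ref))` with delta-method
intervals — covariate-free under the proportional specification, and
exactly consistent with ratios of `incidence_surface` values (a tested
identity). `lrt` compares nested fits (spline vs linear age, spline vs
linear calendar); `subgroup_trend_test` adds subgroup main effects plus
calendar×subgroup interactions (education, sex, or entry-age group) and
reports the interaction LRT.

## 6. Ten-state burden projection

Alive states are the eight combinations of CVD × cognitive impairment ×
functional impairment; dementia is the two states with both impairments;
two absorbing death states split CVD from non-CVD causes, which is how
non-CVD competing mortality is represented. Within a one-year cycle, death
competes first (cause-specific forecast rates scaled by a state's relative
mortality), then each absent attribute is gained independently with
probability `1 − exp(−h)`; impairments and CVD never revert. This
structure is config-encoded (rate functions are injectable) and documented
as an approximation: it does not claim structural identity with any
specific published compartmental model.

Incidence scenarios multiply transitions *into* dementia states by
`m^(year − 2018)` on the rate scale — `p → 1 − exp(−m^(y−2018)·(−log(1−p)))`
— which keeps probabilities in [0, 1] and matches the meaning of a relative
annual change in a rate; the freed or added mass goes to the diagonal, and
a negative residual is an error rather than a silent renormalisation.
Multipliers 1.028 ("upward"), 0.973 ("downward") and 1.0 ("constant")
are the package defaults.

Mortality forecasts come in three variants: (i) a two-dimensional P-spline
— tensor-product cubic B-splines over age × year (5-year knot spacing),
second-order difference penalties per dimension, penalised Poisson IRLS,
smoothing chosen on a BIC grid (`10^0 … 10^4` per dimension), with the year
basis extended to the horizon at zero weight so the penalty propagates the
trend (linear in its null space); (ii) rates frozen at the last data year;
(iii) a log-linear Poisson regression per cause with an age factor.
Degenerate-input conventions: an unpenalised saturated fit reproduces raw
rates exactly; all-zero death rows are handled by the offset convention;
negative exposures are rejected.

Initial occupancy and entrants ship as synthetic, function-generated
fixtures shaped like a national pyramid (flagged as synthetic; real tables
drop in through the same array layout). Uncertainty bands are parametric:
seeded lognormal draws of the annual multiplier propagated through the full
projection; published projection intervals may include more sources than
this, so the bands are labelled as parameter-only.

## 7. The synthetic cohort generator

The generator emulates: a biennial nine-wave panel (mid-2002 to mid-2018)
with refreshment entrants at waves 3, 4, 6, 7 and 9; a latent three-state
process whose onset intensity follows a piecewise log-linear calendar trend
— 5% annual decline to 2008, 2.8% annual increase after, matching the
scenario rates used elsewhere in the package — with Gompertz age effects,
sex effects on mortality, education effects on onset, and optionally
education-specific post-break slopes; five cognitive domain scores shifted
under dementia, education-dependent healthy means; ADL dependency counts;
an absorbing doctor-diagnosis report with imperfect sensitivity and high
specificity; proxy interviews for a fraction (default 30%) of
dementia-state waves with IQCODE-like scores (the fraction is a package
choice, not a published quantity); and exact death dates. Post-onset
mortality is 5× by default — a deliberate, high-but-plausible value for a
moderate-to-severe case definition that makes the death-interval bias
clearly visible in tests.

Simulation is exact: event times are drawn by thinning against a
per-person dominating rate (age at horizon, maximum of the piecewise
calendar trend over the remaining window), so there is no discretisation
bias to confound oracle comparisons. Ages advance continuously and
measurements use age at interview.

Not emulated: survey weights, household clustering, item-level
nonresponse, interview-date jitter within waves, ethnicity, and
non-mortality attrition. Passing tests on this generator therefore
demonstrate correctness of the estimators under the stated process — not
robustness to the sampling complications of real panel studies.

## 8. Problem sizes and test design

The package's simulation studies are sized to what the statistics need
rather than to any fixed runtime: the bias-correction study uses 25
replicates of n = 5000 with constant intensities (naive undershoot,
interval coverage, and naive-vs-corrected proximity asserted with
binomial-consistent bounds scaled from the nominal 95% level); the
coverage study uses 50 replicates of n = 2000 with the V-shaped trend and
checks empirical coverage of both calendar slopes against [0.90, 0.99];
oracle checks run 10⁶ Monte-Carlo trajectories at the primary parameter
set and 2×10⁵ at four others, within three binomial standard errors. The
measurement layer in these studies is set to full separation (large score
shift, deterministic ADL, no false diagnoses) so that the properties under
test — interval censoring and death bias — are isolated from
misclassification, which has its own dedicated tests.

## 9. Known limitations

* The hidden-Markov engine exploits the progressive three-state structure;
  it does not generalise to recovery transitions or more living states
  without reworking the closed-form matrix.
* Observed-information standard errors are asymptotic; no profile or
  bootstrap intervals are provided.
* The piecewise-constant covariate approximation leaves an O(Δt) bias
  under the start-of-interval convention; use the midpoint option when the
  covariate trend within intervals matters.
* The projection's transition structure and its initial-occupancy fixtures
  are synthetic stand-ins; absolute projected counts are only meaningful
  once real population, prevalence and transition inputs are supplied.
* Emission probabilities near the boundary make their logit-scale standard
  errors uninformative; interpret `ε̂ → 0` structurally, not through its CI.
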