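---
title: "Validating competing-risks prognostic models on synthetic registry cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating competing-risks prognostic models on synthetic registry cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrisk)
```

## The model

pcrisk evaluates and validates two-cause prognostic models of the form
used by long-term prostate-cancer decision aids.  A model configuration
(a `coefficient_set`) declares, for each cause — prostate cancer (`pc`)
and everything else (`npc`) — beta coefficients on the log-hazard scale
with their covariate transforms, plus annual baseline hazard rates
$h_{0k}(u)$ for years $u = 1, \dots, 15$ treated as piecewise constant
within years.  For a patient with prognostic index
$PI_k = \sum_j \beta_{kj} x_j$, the annual cause-specific hazard is
$\lambda_k(u) = h_{0k}(u) e^{PI_k}$, with a hazard ratio multiplying the
cancer cause under the radical-treatment scenario.

Cumulative incidence is computed by the exact decomposition for
piecewise-constant hazards:
$$S(t) = \exp\Big(-\sum_{u \le t} \lambda_\bullet(u)\Big), \qquad
CIF_k(t) = \sum_{u \le t} S(u-1)\,
\frac{\lambda_k(u)}{\lambda_\bullet(u)}\,
\big(1 - e^{-\lambda_\bullet(u)}\big),$$
where $\lambda_\bullet = \lambda_{pc} + \lambda_{npc}$.  This identity
is exact, not an approximation: the probability mass dying in year $u$,
$S(u-1)(1 - e^{-\lambda_\bullet(u)})$, is split between causes in
proportion to their hazards, which is the distribution of the minimum
of two independent piecewise-exponential clocks.  Consequently
$CIF_{pc} + CIF_{npc} + S = 1$ holds to machine precision at every grid
point, and the single-cause ($CIF = 1 - e^{-ht}$) and symmetric
two-cause ($CIF_k = (1-e^{-2ht})/2$) closed forms drop out as special
cases; both are enforced in the test suite at `1e-9`.

Whether the original web tool's baseline hazard is smooth or annual is
not something an external validation can observe; the annual
piecewise-constant form is adopted here because it matches the
granularity at which such tools report survival and makes the
competing-risks algebra exact.

### Assumptions

* The two cause-specific processes are conditionally independent given
  covariates (two latent clocks).  This is the standard cause-specific
  hazard framework; it is untestable from observed data alone.
* Proportional hazards on each cause over the 15-year horizon.
* The treatment effect enters only as a hazard ratio on the cancer
  cause under radical treatment.  Men on androgen deprivation
  monotherapy are evaluated with the conservative-scenario hazards by
  default (`adt_hr_pc = 1`), since the underlying tool models
  conservative vs radical only; the multiplier is configurable because
  published validations report over-estimated cancer mortality in that
  subgroup.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `radical_hr_pc` | hazard ratio | 0.65 (illustrative set) | plausible radical-treatment effect on the cancer cause |
| `adt_hr_pc` | hazard ratio | 1 | ADT men scored with conservative hazards; configurable |
| `ppc_mode` | — | `excluded` | biopsy involvement is optional in the model; ~36% missing in registries |
| `horizon_cap` | years | 15 | the model's prediction horizon |
| `quintiles` | groups | 5 | conventional risk-grouping for calibration |
| `psa_max` | ng/ml | 100 (strict `<`) | inclusion rule; also truncates the PSA generator |

The bundled `illustrative_coefficients()` set is **not** the published
tool's coefficients (those belong to its development study and are not
printed in validation reports).  Its structure mirrors the real tool —
age and log-PSA terms, grade-group and stage indicators and an optional
biopsy term on the cancer cause; age and comorbidity on the other-cause
hazard — and its magnitudes were fixed once so that the default
synthetic cohort reproduces registry-scale crude mortality (about 1.4
and 4.4 deaths per 100 person-years).  No empirical claim about the
published tool rests on these numbers; every acceptance-level check
rests on closed forms, simulator oracles, or published arithmetic.

## What the synthetic generator emulates — and what it does not

`sample_covariates()` draws covariates independently from marginals
matching a 2000–2010 nationwide registry baseline table: age normal
(68.8, SD 8.83, truncated to 35–100), PSA log-normal solved to mean
15.7 / SD 17.0 and truncated to (0, 100) — right-skewed, as the mean
far above the typical value implies — grade-group, stage, treatment and
comorbidity frequencies taken directly from the table's counts, and a
Beta(1.6, 2.4) biopsy-cores fraction missing for 36% of men.
`simulate_outcomes()` draws two latent piecewise-exponential event
times from the truth's cause-specific hazards (the radical hazard ratio
applied as treated), a diagnosis date Beta(0.85, 7)-skewed across the
2000–2010 accrual window, and censors administratively at end-2016.
The accrual skew and the illustrative baseline hazards were tuned once,
jointly, to land median follow-up near 14 years and crude rates near
1.38/4.43 per 100 person-years, then frozen; hazards beyond year 15
continue at the year-15 rate.

Deliberately *not* emulated: joint covariate dependence (grade, stage
and PSA are correlated in real registries; only marginals are published
so only marginals are matched), calendar-time treatment trends,
treatment switching, cause-of-death misclassification, and emigration
censoring.  A green self-consistency test therefore establishes that
the pipeline's algebra and bookkeeping are correct under the stated
generative world — it does not establish that the illustrative model
would validate well on real registry data, and the c-indices the demo
prints (≈0.72 for cancer death) are properties of the independent-
covariate synthetic world, not of any published tool.

Random streams for covariates, accrual and latent event times are
seeded separately, so changing the censoring configuration never
perturbs latent event times at a fixed seed.

## Discrimination

`harrell_c()` implements Harrell's concordance for right-censored data:
comparable pairs are those whose strictly earlier observed time is an
event of the target cause; at tied times an event–censored pair is
comparable, two tied events are not; tied scores count one half.
Competing-cause deaths are treated as censoring at the death time for
cause-specific concordance — the standard Harrell construction, stated
explicitly because validation reports are usually silent on it.  The
model's score is its predicted 15-year cumulative risk; comparator
systems (CAPRA points, EAU and NCCN-style strata) are scored by their
ordinal labels directly.

The standard error is the exact leave-one-out jackknife.  Rather than
recomputing $c$ $n$ times, per-patient pair aggregates are accumulated
in the same $O(n^2)$ C++ pass, from which every $c_{(-i)}$ follows in
closed form; the test suite verifies exact agreement with a literal
leave-one-out recomputation and with exhaustive pair enumeration, and
cross-checks the point estimate against the survival package.
`compare_c()` tests score differences with a paired z-test on the
per-patient jackknife values — a documented, assumption-light
substitute for whatever closed-form a particular validation's software
used, not a claim about it.

## Calibration

Expected death counts are sums of per-patient predicted cumulative
risks, interpolated linearly between the annual grid points (monotone,
simple, with error bounded by the annual increments).  One design
decision deserves emphasis: *at what time is each patient's predicted
risk evaluated?*  Evaluating at the observed follow-up time — death
time for the deceased — systematically underestimates expected counts
(a patient dying in year 2 contributes only $CIF(2)$ although they
contributed a whole death), and with ~35% cumulative mortality the
deficit is far larger than Monte-Carlo noise: self-validation would
appear miscalibrated.  Under administrative censoring the *potential*
follow-up time (diagnosis to the registry cut-off) is known for every
patient, died or not, and evaluating expected risk there makes the
expected count an unbiased estimator of the observed count under a
correct model.  `expected_events()` therefore uses potential follow-up
whenever an administrative censoring date is supplied (the pipeline
default) and falls back to observed follow-up otherwise; the choice is
recorded in the run log.

`quintile_calibration()` ranks patients by predicted risk (ties broken
by stable input order), cuts equal-count groups, and computes the
grouped statistic $\chi^2 = \sum_g (O_g - E_g)^2 / E_g$ with $G - 1$
degrees of freedom — the grouped-survival variant in the May–Hosmer
tradition; the originating literature admits several variants, so the
statistic and its degrees of freedom are a documented, configurable
choice rather than a reconstruction.  Because $O_g$ is a sum of
Bernoulli variables with variance below the Poisson variance $E_g$, the
test is mildly conservative at high per-patient risks; the acceptance
suite confirms non-rejection at (at most) the nominal rate under the
truth and >90% rejection when true cancer hazards are inflated 1.5-fold
at n = 50,000.

Subgroup calibration reports the percent difference between observed
and expected counts.  Published tables do not pin down the denominator,
so the convention is configurable (`|E−O|/O` by default, `/E` or `/n`
optional) and always recorded alongside the results.

## Comparator classifiers

The CAPRA point schedule and the EAU/NCCN strata ship as versioned
configuration objects whose bundled defaults follow the cited guideline
sources; the validation context contributes exactly two imputations,
wired in as defaults: clinical T2 without sub-stage is scored as T2a,
and a missing biopsy-cores fraction falls in CAPRA's "< 34%" band.
Grade groups map to Gleason patterns as GG1→(3,3), GG2→(3,4),
GG3→(4,3), GG4→(4,4), GG5→(4,5); stages above T3a map to each system's
highest stage band.  The NCCN-style table is an explicit approximation:
very-low-risk criteria need core counts and PSA density, which
registries of this era lack, so that stratum collapses into low; which
NCCN edition a given validation used is typically unstated, and the
configuration-file design defers that choice rather than guessing.

## Numerical and degenerate-input choices

* Years with both hazards zero contribute nothing to any CIF; all-zero
  configurations yield $(0, 0, 1)$, and a cohort with zero person-years
  is an error rather than a `NaN` rate.
* Exact ties between the two latent clocks (probability zero under
  continuous draws) resolve to the cancer cause.
* Concordance with no comparable pairs is an error (undefined), not 0.5.
* A risk group with zero expected events aborts with advice to merge
  groups rather than dividing by zero.
* Crude rates are events per 100 person-years to two decimals (baseline
  tables label them "per patient year", but the printed magnitudes only
  arise per 100); raw unrounded rates are kept alongside, and
  rate × person-years / 100 recovers the event count exactly.
* Records excluded by filters are counted once each in the exclusion
  total even when several fields are missing; per-field tallies are
  reported separately and may sum to more than the total.
* Records missing the metastatic flag are excluded by default; an
  explicit `missing_m_as_m0` flag treats them as non-metastatic, and
  either behaviour is logged.

## Known limitations

* Coefficients are configuration: the package validates *a* model on
  *a* cohort; it does not contain the published tool's coefficients and
  cannot reproduce registry-specific headline results (the registries
  are access-restricted).
* Independent-covariate synthetic cohorts understate the discrimination
  and overlap structure of real cohorts.
* No time-dependent AUC, Brier score or decision-curve analysis; the
  scope is the discrimination/calibration repertoire of a classical
  external validation.
* Endpoints other than death (metastasis, hormone-therapy initiation)
  and treatment transitions after 12 months are out of scope.
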