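---
title: "Methods: projecting lifetime cancer risk from CT utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting lifetime cancer risk from CT utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctlar)
```

## The question and the modeling approach

Lifetime cancer risks from low-dose radiation cannot be measured directly
on contemporary imaging populations — that would require decades of
follow-up — so the accepted approach is risk projection: take
dose–response models fitted to irradiated cohorts (primarily the Japanese
atomic-bomb survivors, as synthesized in the BEIR VII report), apply them
to the organ doses a population actually receives, and accumulate excess
risk over remaining lifetime with death as a competing risk. `ctlar`
implements that pipeline end to end for national CT utilization, with
every input (utilization mix, organ doses, life tables, baseline cancer
rates, risk coefficients) supplied as configuration and shipped with
synthetic defaults so the whole analysis is runnable and testable without
any restricted data.

The pipeline stages and the units that flow between them:

| stage | input | output |
|---|---|---|
| `generate_registry()` | `registry_config()` | exam-level records, organ doses in mGy |
| `summarize_strata()` | exam records | 418 strata: counts, proportions, dose mean/SD |
| `scale_to_national()` + `apply_eol_exclusion()` | strata, national totals | exam counts per stratum |
| `lar_per_exam()` | strata, draws | excess cancers per exam, per site |
| `project_cancers()` | counts × risks | national projections, 90% limits |
| `scenario_suite()` | projection config | eight sensitivity rows |

## The risk model

For a solid cancer site, the excess relative risk and excess absolute
risk at organ dose $D$ (Gy), exposure age $e$ and attained age $a$ are

$$\mathrm{ERR}(D,e,a) = \beta_s D\, e^{\gamma e^*} (a/60)^\eta, \qquad
e^* = \frac{\min(e,30)-30}{10},$$

with a separate $(\beta, \gamma, \eta)$ set for the EAR model. Leukemia
(red bone marrow dose) uses the linear-quadratic form
$\beta_s D (1+\theta D)\, e^{\gamma e^* + \delta \ln(t/25) + \varphi e^* \ln(t/25)}$
in time since exposure $t$. The site's lifetime attributable risk is the
annual sum

$$\mathrm{LAR}(D,e) = \sum_{a=\lfloor e\rfloor+1}^{100}
 w_{\mathrm{lat}}(a-e)\; M(D,e,a)\; \frac{S(a)}{S(e)},$$

where for solid sites
$M = [\,w\,\mathrm{ERR}\,\lambda(a) + (1-w)\,\mathrm{EAR}/10^4\,]/\mathrm{DDREF}$
and for leukemia the same mix without the DDREF divisor. $\lambda(a)$ is
the baseline incidence rate (cases per person-year), $S$ the sex-specific
survival curve, $w$ the transfer weight between multiplicative and
additive risk transport. Per-exam risk for a stratum evaluates each site's
LAR at the stratum's mean organ dose (mGy/1000) and the midpoint age of
its age group; national counts multiply by included examinations.

Assumptions worth stating plainly: risks transfer from the source cohorts
to the target population as a fixed ERR/EAR mixture; dose response is
linear (solid) or linear-quadratic (leukemia) with no threshold; organ
dose means are sufficient statistics per stratum (within-stratum dose
variability is not propagated by default); exposures are evaluated
independently (no per-patient dose accumulation across repeat exams —
risks are linear, so totals are unaffected, which is also why
patient-based and exam-based aggregation agree, see
`patients_vs_exams_equivalence()`).

## Parameters that matter

* **Risk coefficients** (`default_risk_config()`): one row per
  (site, sex); $\beta_{ERR}$ per Gy, $\beta_{EAR}$ per $10^4$
  person-year-Gy, age modifiers, $\theta$ (per Gy, leukemia only),
  transfer weight. The eleven classical-site values are our transcription
  of the BEIR VII preferred models; the six additional sites and the
  remainder category reuse the pooled residual-site coefficients because
  no published per-site parameterization is available for them — this is
  the largest single source of structural uncertainty for those rows, and
  the table is deliberately plain data so users can substitute their own.
* **Transfer weights**: 0.7 ERR / 0.3 EAR by default, lung 0.3/0.7,
  breast EAR-only, thyroid ERR-only, the conventional choices.
* **DDREF**: lognormal, median 1.5, $\sigma$ fitted by least squares to
  the 90% interval (1.1, 2.3). That interval is not log-symmetric around
  1.5, so no lognormal hits both endpoints; the fit (σ ≈ 0.248) favors the
  upper endpoint because absolute errors there are larger. We kept the
  documented least-squares criterion rather than switching to log-space
  fitting, and the sampler's *median* — the quantity with a stated
  tolerance — is exact.
* **Latency** (`default_latency_config()`): phase-in midpoints are
  triangular T(5, 7.5, 10) years for solid cancers, T(3, 5, 7) thyroid,
  T(2, 2.25, 2.5) leukemia, with 5–95% windows 4.0–11.0, 2.5–7.6 and
  0.4–4.1 years.
* **Draws**: `n_draws = 500` by default; limits are 5th/95th empirical
  percentiles of per-draw group totals. One draw set is shared across all
  strata (systematic parameter uncertainty); sampling independent draws
  per stratum would shrink national limits toward zero, which is not what
  a parameter-uncertainty interval means.
* **Coefficient uncertainty**: one lognormal multiplier per site and
  model class, geometric SD 1.3, shared across sexes. The source
  coefficients are published without usable per-site uncertainty for this
  pipeline, so the GSD is a single realism-level choice, made once.

## Numerical choices

* **Latency ramp shape**: the published inputs give the window and the
  midpoint distribution but not the ramp; we use a logistic in $t$ with
  weight 0.5 at $\mu$ and steepness $k = 2\ln 19 / (\text{window width})$,
  which traverses 5%→95% across the window exactly when $\mu$ is modal.
  For the slightly asymmetric thyroid window the 5% point lands within
  0.003 of the window start.
* **Lifetime horizon**: annual summation from $\lfloor e\rfloor+1$ to
  100, matching life-table granularity; LAR(·, 100) = 0 by construction,
  and the closed form $\lambda D (100-e)$ is reproduced exactly under flat
  survival, constant baseline and unit weights.
* **Stratum age**: group midpoint (e.g. 50–59 → 54.5, `<1` → 0.5),
  unbiased under a uniform within-group age distribution.
* **Rounding**: national allocation uses largest-remainder rounding so
  stratum exam counts sum exactly to the configured total. Volume
  scenarios multiply allocated counts rather than re-allocating a scaled
  total, so a ±10% volume scenario changes projections by exactly ±10%
  instead of exact-to-rounding. Displayed tables round counts ≥1000 to the
  nearest 100 and 10–999 to the nearest 10 (half-up); stored values are
  never rounded.
* **Seeds**: every stage derives its seed from the root seed via a hash
  (`split_seed(seed, stage)`), so stages are independently reproducible
  and the whole chain is byte-stable under a fixed seed.
* **Degenerate inputs**: zero dose and zero-probability flags propagate
  to exact zeros; SD 0 dose distributions are point masses; strata with
  all records flagged for exclusion raise errors rather than returning
  empty tables.

## What the synthetic data emulate — and what they do not

`registry_config()` defaults emulate the statistical structure national
analyses rest on: ~3.3% pediatric exam share, 28.5% multiphase flag,
exams-per-patient means 1.1–1.7 rising with age (count = 1 + Poisson, so
the median is 1 in every cell), last-year-of-life fractions from under 1%
in young children to ~40% past age 90, organ-dose means with region,
dose-tier, age and sex structure (infant head doses highest, marrow dose
from head CT falling with age) and within-stratum lognormal spread with
CV 0.58. Life tables are Gompertz–Makeham; baseline incidence uses
power-law-in-age templates with a childhood-peaked leukemia term, with
magnitudes ordered like US rates.

They are stand-ins, not calibrated reconstructions: dose means are
magnitude-realistic inventions, not measured dosimetry; baseline rates
are smooth templates, not registry rates; the 26 category names are a
constructed vocabulary (13 adult-only, 8 child-only, 5 shared) chosen to
reproduce the 18-adult/13-child applicability counts, because the actual
category list is not public. Consequently passing tests demonstrate the
*mechanics* — stratum accounting, dose-response linearity and curvature,
survival and latency weighting, LHS stratification, scenario algebra,
determinism — and the realistic *orders of magnitude*, but the absolute
projected totals shift with the synthetic inputs and should not be read
as national estimates. With the shipped defaults the pipeline projects
roughly 0.4 excess cancers per 1000 examinations; analyses built on
measured doses and registry baseline rates land higher, and users
supplying real tables inherit the difference deliberately.

The 2-year end-of-life map is likewise synthetic (1.6× the 1-year map,
capped at 1), and the pre-2020 distribution profile is a mild tilt of the
baseline mix; both are pluggable.

## Problem sizes

Test and acceptance runs use sizes chosen to make sampling error
negligible relative to the tolerances tested: registries of 20,000–70,000
patients (≈30,000–105,000 exams) for recovery and goodness-of-fit checks,
500 Latin hypercube draws for the property suite and the acceptance
script, and 100 random configurations for the LAR-versus-oracle
comparison at 1e-10 relative tolerance.

## Known limitations

* The six non-classical sites share pooled coefficients; their site
  labels should be read as "pooled residual risk attributed to this
  organ's dose".
* Organ-dose uncertainty (the per-stratum SDs) is not part of the LHS by
  default; the SDs are carried through summaries for users who want to
  add it.
* No calendar-time utilization forecasting, no per-patient longitudinal
  dose accumulation, no dosimetry (doses are inputs), no causal
  attributable-fraction claims.
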