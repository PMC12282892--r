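---
title: "Methods: comparing risk-based and benefit-based statin eligibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing risk-based and benefit-based statin eligibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinbenefit)
```

## The problem

Statin eligibility in primary prevention is usually decided by an
absolute-risk rule: treat if the predicted 10-year cardiovascular (CVD)
risk is at least some threshold, typically 10%. Because statin benefit is
mediated largely by LDL-cholesterol lowering, absolute risk is an
imperfect proxy for benefit: a high-risk person with low LDL-C has little
to lower, while a moderate-risk person with high LDL-C can expect a large
absolute risk reduction. The alternative studied here treats by predicted
*individual absolute risk reduction* (iARR).

This package implements both rules, calibrates them to prevent the same
number of population events so they can be compared fairly, and reports
how differently they select people.

## The model chain

For each person with covariates $x$ and sex $s$:

1. **Untreated 10-year risk.** A Cox-type survival model,
   $\mathrm{risk}_0 = \bigl(1 - S_{0,s}^{\exp(LP)}\bigr) / d_s$ with
   $LP = \sum_k \beta_{k,s}\,(t_k(x_k) - \bar x_{k,s})$. The divisor
   $d_s$ recalibrates for systematic overestimation in the target
   population (defaults 1.59 for men, 1.72 for women) and is applied to
   the final predicted risk, not the linear predictor. The result is
   clipped to $[0, 0.999]$ so reciprocals stay finite.
2. **LDL-C reduction.** $\Delta = p \cdot \mathrm{LDL}_0$ with $p = 0.40$
   for moderate-intensity therapy (0.30 in sensitivity analyses).
3. **Relative risk.** A per-mmol/L relative risk $r$ — constant by
   default, optionally interacting with baseline risk as
   $r = \exp(a + b\,g(\mathrm{risk}_0))$, $g \in \{$identity, log,
   logit$\}$ — raised to the LDL-C reduction in log space:
   $RR = \exp(\Delta \ln r)$.
4. **Benefit.** $\mathrm{iARR} = \mathrm{risk}_0 (1 - RR)$ and
   $\mathrm{iNNT} = 1/\mathrm{iARR}$, carried unrounded; tables round to
   integers at display time.

Risk strata are the guideline categories low (<5%), borderline
(5–<7.5%), intermediate (7.5–<10%), high (≥10%), with inclusive lower
bounds; eligibility thresholds are likewise inclusive.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ldl_reduction_prop` | 0.40 | fraction of baseline LDL-C | standard moderate-intensity effect; 0.30 as a conservative sensitivity value |
| `rr_constant` | 0.78 | RR per mmol/L | documented fixture; the package deliberately does not hard-code a meta-analysis value, users should transcribe one for real-data work |
| `recalibration_divisor` | 1.59 (M) / 1.72 (F) | — | published predicted/observed ratios for the target population |
| risk threshold | 0.10 | 10-year risk | conventional high-risk cut-off; 0.075 for intermediate-or-higher |
| bootstrap `reps` | 1000 | — | percentile CIs stabilise near 1000 replicates at these sample sizes |

The risk-model coefficient set is **pluggable** (JSON via
`read_risk_model()`). The shipped set (`default_risk_model()`, also at
`inst/extdata/risk_model_standin.json`) is a *synthetic stand-in*: its
shape (age, SBP, total cholesterol, smoking, diabetes; sex-specific
baselines) matches published laboratory-based CVD equations, but its
numbers were chosen only to give plausible gradients in a middle-aged
cohort. The diabetes coefficient is carried in the spec but always
evaluates to zero because diabetics are excluded from the analytic
cohort — this keeps the spec shape faithful to equations that include the
term without it ever affecting results.

## The two threshold principles

**Comparable event prevention.** Events averted by a strategy are the
deterministic expectation $\sum_{i\ \mathrm{eligible}} w_i\,
\mathrm{iARR}_i$ (survey weight $w_i$ = persons represented). The benefit
threshold is calibrated so the benefit rule averts the same events as the
risk rule. The search grid is the sorted distinct observed iARR values
plus their midpoints (the eligible sets are exactly the
threshold-consistent subsets, so this grid is exhaustive); ties are
broken toward the *higher* threshold, i.e., fewer people treated for
equal prevention, consistent with the efficiency framing. Thresholds are
carried at full precision and also reported rounded to 0.1 percentage
point for display.

**Minimum-benefit expansion.** The benefit threshold is set to the
smallest iARR observed among risk-eligible people. Every risk-eligible
person trivially satisfies it, so the expanded strategy is always a
superset of the risk strategy.

## Projection and uncertainty

Events averted are projected deterministically (expected events), not by
simulating Bernoulli outcomes: the quantity of interest is the expected
population impact, and person-level aleatory noise would only blur it.
Sampling uncertainty is estimated by a person-level bootstrap: resample
$n$ records with replacement, weights carried with the records, recompute
the statistic, take 2.5th/97.5th percentiles. Replicates where a
statistic is undefined (e.g., zero events averted) are counted and
excluded. The replicate count and the percentile method are package
choices — the number of replicates and CI method were genuinely open, and
the percentile method was chosen for its lack of distributional
assumptions at these sample sizes (Monte-Carlo coverage of the
events-averted CI is verified ≥93% at nominal 95% in the test suite).
Complex survey design (strata, clusters, replicate weights) is *not*
honoured; weights are treated as frequency weights throughout.

Summary conventions: weighted median is the *lower* weighted median
(smallest value whose cumulative weight reaches half the total); weighted
SD uses the frequency-weight convention
$\sqrt{\sum w (x-\bar x)^2 / (\sum w - 1)}$; average NNT is
$\sum w / \sum w\,\mathrm{iARR}$ over the eligible; maximum iNNT is the
reciprocal of the smallest eligible iARR.

## What the synthetic generator does and does not emulate

`generate_cohort()` reproduces the *structure* of the analytic sample: n
= 7287 by default, ~51.7% women, truncated-normal age with mean 57 on
[40, 80], SBP linear in age, LDL-C conditional on total cholesterol and
truncated to [1.8, 4.9) mmol/L with `tc >= ldl` enforced, sex-specific
smoking, uniform weights summing to 324.6 million. Distribution
parameters without a published anchor (SBP/TC/HDL means and SDs, the
LDL-given-TC ratio, smoking and exclusion-flag rates) were set once to
values a cardiovascular epidemiologist would call unremarkable for a
middle-aged East Asian cohort, and are all config-exposed.

It does **not** emulate: the survey's multi-stage sampling design or
design weights (weights are uniform), covariate missingness (records are
complete, so multiple imputation is out of scope), realistic covariate
correlation beyond the two declared links (SBP–age, LDL–TC), or secular
trends. Consequently a green test establishes that the *machinery* is
correct — filters, formulas, calibration, projection, concordance — not
that any published population figure is reproduced. Headline population
numbers depend on the real microdata and the unpublished coefficient set
and are intentionally out of reach; the acceptance suite instead checks
self-contained printed arithmetic plus property/oracle equivalences, and
asserts the qualitative discordance pattern (benefit-only people younger
with higher LDL-C than risk-only people; a 30% LDL-C effect lowering the
calibrated threshold) on a fixed-seed synthetic cohort.

## Numerical choices and degenerate inputs

- Exclusion filtering charges each removed record to the first matching
  reason in the fixed order age, CVD history, diabetes, LDL low, LDL
  high, statin use, so tallies are reproducible when reasons co-occur.
- Interval conventions: age window inclusive [40, 80]; LDL-C half-open
  [1.8, 4.9); all eligibility thresholds inclusive.
- Calibration with an unattainable target (more events than treating
  everyone) is an explicit error; target 0 returns a threshold above the
  maximum iARR (nobody treated, achieved 0).
- `compute_innt()` on a non-positive iARR errors — it signals a person
  with no modelled benefit rather than silently producing `Inf`.
- Risk clipping at 0.999 and RR clipping to (0, 1] keep all downstream
  logs and reciprocals defined.
- Generator and bootstrap save and restore the caller's RNG state, so
  seeded calls do not perturb the session's randomness.

## Known limitations

Benefit is modelled purely through LDL-C lowering: non-lipid statin
effects, adherence, adverse effects, treatment-effect heterogeneity over
time, and statin intensities other than a single proportional LDL-C
effect are not modelled. Only 10-year horizons are supported; no
cost-effectiveness or utility weighting. The stand-in risk model is not
validated against any population and must be replaced for substantive
use.
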