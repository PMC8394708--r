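---
title: "Methods: two-arm cost-effectiveness analysis of CRC screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-arm cost-effectiveness analysis of CRC screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceascreen)
```

## The evaluation

`ceascreen` implements a single-study, cross-sectional economic evaluation
of colorectal-cancer (CRC) screening from the healthcare provider
perspective. Two strategies are compared over cohorts of 100 patients
each: germline genetic testing for hereditary CRC syndromes, and the
immunological faecal occult blood test (iFOBT), the incumbent screening
modality. The chain is:

1. **Provider costing.** Each arm's annual per-patient cost is the sum of
   nine itemised components (building, equipment, human resource,
   administration/overhead, utilities, maintenance, medication,
   consumables, laboratory). Components are produced upstream by either
   top-down costing (aggregate expenditure divided by patients served,
   scaled by mean visits; `top_down_unit_cost()`) or activity-based
   costing (summing the costs of the activities a test directly consumes;
   `activity_based_unit_cost()`). Ledgers in Malaysian Ringgit are
   converted at 4.14 MYR per USD (2019 prices); CPI adjustment to the
   price year is a user-supplied multiplicative index (`cpi_adjust()`,
   default 1, as the bundled dataset is already in 2019 USD).
2. **Effectiveness.** For each arm, stage-specific mean survival times
   $s_k$ (stages $k \in \{I,\dots,IV\}$, 10-year-horizon restricted means
   from a national cancer-survival study, taken as exogenous inputs) are
   multiplied by the stage patient counts $n_k$ to give life-years,
   $LY_k = s_k n_k$. QALYs weight these by the stage mean EQ-5D-5L
   utility, $QALY_k = s_k n_k u_k$. Totals are summed at full floating
   precision; per-patient values divide by $\sum_k n_k$.
3. **Incremental analysis.** Average cost-effectiveness is cost per LY
   and cost per QALY per arm. The ICER compares cohort-level *management*
   costs (stage-wise treatment cost times stage count, plus the cohort
   screening cost) against cohort-level QALYs:
   $ICER = \Delta C / \Delta E$. The $(\Delta E, \Delta C)$ point is
   classified on the cost-effectiveness plane; a strategy that costs less
   and yields more QALYs (southeast quadrant) *dominates* its comparator.
   Trade-off ICERs are classed against GDP-per-capita
   willingness-to-pay bands.
4. **Sensitivity.** A one-way deterministic analysis re-scales costs and
   consequences at discount rates of 3% and 5%.

On the bundled dataset the result is: genetic testing costs more per
patient to deliver (USD 976.26 vs 372.83) but shifts diagnosis toward
early stages (70% of its cohort in stages I–II vs 23% under iFOBT), so
its cohort accrues more QALYs (496.74 vs 343.78 per 100 patients) *and*
costs less to manage overall (USD 600,651.33 vs 615,948.66, because
late-stage treatment is expensive). The ICER is
$-15{,}297.33 / 152.96 = -100.01$ USD/QALY in the southeast quadrant:
genetic testing dominates.

## Utility outcomes

EQ-5D-5L profiles score five dimensions (mobility, self-care, usual
activities, pain/discomfort, anxiety/depression) on levels 1–5. A *value
set* maps a profile to a utility index anchored at 1 for full health.
The package ships an additive value-set interface: a documented toy
linear tariff (`linear_value_set()`, decrement 0.05 per level step,
worst state 0) used for testing and profile synthesis, and a loader for
externally supplied coefficient files (`load_value_set()`). No country
tariff coefficients are bundled; none are needed downstream, because the
effectiveness chain consumes arm-by-stage mean utilities that are inputs
in their own right. A "problem" in a dimension is any level ≥ 2 — the
conventional dichotomisation when a single proportion per dimension is
reported.

The bundled patient-reported outcome summaries (problem proportions,
utility and VAS means/SDs/medians) are stored *as published
aggregates* and passed through, not recomputed: their respondent
denominators are not fully recoverable from the published counts, so no
patient-level reconstruction is attempted.

## Reporting conventions and numerical choices

- **Full precision first, round last.** All arithmetic is at double
  precision; rounding to 2 dp happens at report rendering. This is
  load-bearing: summing per-stage QALYs already rounded to 2 dp gives
  343.79 for the iFOBT arm, while full-precision summation rounds to the
  correct 343.78.
- **Headline cost-per-effect figures** divide the arm cost by the
  per-patient effect *as reported at 2 dp* (372.83/5.21 = 71.56); this
  is the convention under which the published table was built.
  Full-precision variants (`cost_per_ly_full`, 71.55) sit alongside in
  the pipeline output. The sensitivity table follows the same
  convention: scenario cells discount the reported 2-dp base-case cells.
- **Discounting.** The default `"multiplicative"` rule is a one-shot
  cost reduction, value × (1 − r): every published scenario cell equals
  the base case scaled this way (e.g. 976.26 × 0.97 = 946.97). This is
  not conventional compound discounting, so `"exponential"`
  (value / (1 + r)^horizon, horizon defaulting to the 1-year costing
  period) is offered as a documented alternative. One published cell
  (genetic-testing cost at 5%, printed 927.44) is a truncation of the
  computed 927.447 rather than a rounding; tests allow one printed digit
  there.
- **Cost differences.** Per-component between-arm differences carry a
  normal-approximation interval, diff ± 1.96·√(SE²ₐ+SE²ᵦ). The source
  tables also print much narrower intervals whose construction is not
  stated; those are retained verbatim in the bundled dataset
  (`published_differences`) flagged as-published, and the published
  unrounded total difference (603.424) seeds the sensitivity
  difference row. The difference computed from the printed component
  totals is 603.43; the two agree to one printed digit.
- **Plane classification.** Dominance is strict (dominant ⇔ ΔC < 0 and
  ΔE > 0; dominated ⇔ the mirror image); points on either axis are
  reported as `"boundary"` trade-offs, and a zero incremental effect
  yields an undefined (NA) ICER with the classification still reported.
  A bare negative ICER is never interpreted without its quadrant.
- **Threshold bands.** The GDP-per-capita prose convention leaves the
  (1, 2)×GDP interval unassigned; the package follows the WHO-CHOICE
  style bands: ratio < 1 highly cost-effective, 1–3 cost-effective,
  > 3 not cost-effective, with dominance short-circuiting the bands.
  The default GDP per capita is USD 11,414 (Malaysia, 2019); for the
  bundled dataset any positive value yields the same class because the
  new arm is dominant.
- **Display rounding** uses R's `round()` (round-half-even) at 2 dp;
  manifest values are stored at full precision alongside their display
  values.

## The synthetic cohort generator

`generate_cohort()` emulates the patient-level structure the analysis
assumes, so every module can be exercised without any real patient data:

- **Stage assignment** per arm follows the study's stage distributions
  (iFOBT 6/17/54/23%, genetic testing 10/60/25/5% over stages I–IV),
  either multinomially or by exact deterministic allocation (needed for
  exact-reproduction tests).
- **Utilities** are drawn from a normal distribution truncated above at
  1 whose *location is calibrated by root-finding so the post-truncation
  mean equals the arm-by-stage target mean*. Naive truncation at 1 with
  the dispersion used here (SD 0.273, the only published dispersion
  figure) would bias stage means down by up to 0.14 and break parameter
  recovery; calibration keeps the generator unbiased in the mean. The
  realised SD is somewhat below the nominal 0.273 for high-utility
  stages — a known, accepted property.
- **EQ-5D profiles** invert the toy linear tariff (levels chosen so the
  toy index approximates the drawn utility). They exercise the outcomes
  module and carry no clinical claim.
- **VAS** draws are normal (mean 73.58, SD 18.47) clipped to [0, 100].
- **Cost ledgers** (`generate_cost_ledger()`) draw per-patient component
  amounts around an arm's component means, clipped at zero.

With zero utility noise and deterministic allocation, pushing the
synthetic cohort through `cohort_to_stage_table()` and `stage_qalys()`
reproduces the bundled per-patient LY/QALY values exactly; with
multinomial sampling at 10,000 patients per arm (fixed seed) they land
within 2%. Problem sizes in the test suite (up to 20,000 patients for
the calibration check) keep the full run in a few seconds.

What the generator does **not** emulate: demographic covariate effects
on utility, correlation between utility and VAS, within-stage survival
heterogeneity, or the published patient-reported outcome table (whose
respondent set is wider than the costed cohorts). Passing tests
therefore validate the pipeline's arithmetic and its statistical
plumbing, not the clinical realism of any synthetic patient.

## Known limitations

- Survival means are lump-sum restricted means; no survival modelling,
  no Markov state-transition structure, and no probabilistic sensitivity
  analysis (CEAC) are performed — the evaluation is a deliberate
  group-level comparison.
- The published per-component confidence intervals cannot be reproduced
  from the published SEs under any standard formula and are carried
  as-published only.
- Inferential group comparisons (chi-square, Mann–Whitney) and the
  utility–VAS correlation require patient-level data that are not
  published, and are out of scope; `summarize_outcomes()` is
  descriptive only.
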