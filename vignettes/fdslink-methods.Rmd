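---
title: "Methods: from formulary decision support to adherence in three links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from formulary decision support to adherence in three links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the chain of models

Formulary decision support (FDS) in e-prescribing software shows the
prescriber a medication's benefit tier — passively (a symbol next to the
drug name) or interruptively (an alert proposing preferred-tier
alternatives). If FDS shifts prescribing toward preferred brands, patients
pay smaller copayments, and cheaper medications are taken more faithfully.
`fdslink` implements that causal chain as three separately estimated
statistical links plus a projection calculator that composes them:

1. **FDS to tier.** A marginal logistic model for the probability that a
   new prescription lands on the preferred brand tier, with medication
   class, prescriber usage group (non-user, low user below a 30%
   e-prescribing rate, high user above it), exposure period (pre-FDS,
   non-interruptive only, combined interruptive + non-interruptive), and
   the group-by-period interactions. The difference-in-differences effect
   of interest is the high-user by combined-FDS interaction odds ratio.
   Claims cluster within prescriber, so the model is fitted by
   generalized estimating equations (GEE) with an exchangeable working
   correlation and robust standard errors.
2. **Tier to copayment.** A linear model of the transformed monthly
   copayment on tier, class and their interaction, so each class-by-tier
   cell is exactly representable. Cell estimates are back-transformed to
   dollars.
3. **Copayment to adherence.** A linear mixed model of the 180-day
   proportion of days covered (PDC) on the transformed monthly copayment,
   class, income stratum and more-than-daily dosing, with a prescriber
   random intercept. Coefficients read as absolute PDC changes.

The projection layer converts the interaction odds ratio into an absolute
probability shift at a baseline preferred-tier rate, the shift into an
expected monthly copayment change `delta_p * (c_non - c_pref)`, and the
copayment change into a PDC change through the fitted slope. An external
variant substitutes survey copayments ($29 preferred / $52 non-preferred)
and a cost-sharing elasticity (4% use change per 10% cost change,
midrange of a published meta-analytic range of 2-6%) for the study's own
second and third links, applied at a 60% baseline PDC.

## Cohort construction

Raw dispensings pass through a fixed exclusion cascade, in this order:

* **Minimum supply.** Claims under 15 days supplied are dropped (trial
  starts and data errors). Because the filter sits upstream, a dropped
  trial fill also cannot block a later claim's new-user status; a
  `min_days_first` switch restores the alternative reading.
* **New-user washout.** A claim is an *index* claim when the patient had
  no same-class claim in the prior 180 days ("six months" is taken as 180
  days, matching the adherence window; calendar-month arithmetic would be
  ambiguous). Claims of the other class never block. Claims in the first
  180 days of the extract face the same left-censored lookback the source
  data had.
* **Adherence eligibility.** Index claims from 2006 are flagged (not
  dropped): their 180-day window would run past the extract, so they
  enter tier analyses but not adherence analyses.

Non-adopting prescribers receive a *synthetic* activation date sampled
with replacement from adopters' actual dates, so controls split into the
same three periods and secular trends cancel in the
difference-in-differences contrast. Boundaries are inclusive on the
exposed side: a fill on the activation date counts as post-activation,
and a fill on the interruptive go-live date (2005-09-16) counts as
combined-FDS. The three labels partition all dates. Ties at the 30% usage
threshold classify upward (high).

Monthly copayment is standardized as `copayment * 30 / days_supplied`;
the 30-day month is the claims-analysis norm and the source never states
its own normalization.

## The PDC engine

PDC is the fraction of the 180 days starting at the index fill (day 0
counts as covered day 1) on which any same-class medication was on hand,
pooling tiers and products within the class. Overlapping supply is
handled by the dominant stockpiling convention — a refill dispensed while
supply remains is queued to start when the previous supply runs out —
with a `truncate` alternative that discards overlap, both exposed and
both tested against a literal day-by-day simulation. Coverage beyond the
window is cut off; windows that run past the extract end are computed but
flagged right-censored. The implementation reduces the sequential
recursion to grouped cumulative sums and maxima, so hundreds of
thousands of windows compute in about a second; patients with several
same-class index claims fall back to the sequential engine.

## The synthetic world

Real claims in this setting are proprietary, so the generator emulates
their statistical structure with explicit ground truth
(`true_parameters()` returns it keyed exactly like the fitted output).
Defaults are the studied world:

* **Rosters.** 1570 / 187 / 74 prescribers (non / low / high users), 8
  patients each (14,410 patients over 1831 prescribers in the source).
  Low-user usage rates are uniform below 0.30; high-user rates are
  `0.30 + 0.70 * Beta(2, 2.52)`, mean 0.61 as reported. Activation dates
  interpolate the reported adoption-date quartiles (June 2 / August 4 /
  September 29, 2005) across calendar 2005. Income strata use the
  reported 18 / 58 / 24 marginals; age, sex, specialty and practice size
  follow the published descriptive margins and are plumbing, not effects.
* **Tier choice.** A (group x period x class) probability table. The
  default calibration anchors the intercept so the pooled non-user
  pre-FDS cell is 63%, takes group and period main effects from the
  pooled unadjusted table, sets the four interaction odds ratios to their
  published adjusted values — so the high-user x combined-FDS truth is
  exactly 1.9 — and puts inhaled steroids 4.1 above ARBs in odds within
  every cell. A second calibration (`tier_cells_table2()`) instead solves
  class-specific cells so every pooled unadjusted cell is matched
  exactly (its high-user combined-FDS cell is 78%); the two targets are
  mutually inconsistent by about 0.05 in the interaction odds ratio, so
  the package exposes both rather than splitting the difference. A
  uniform calibration gives null configurations for type-I-error checks.
  Non-adopters' secular trend runs off a latent per-prescriber trend
  date (`sim_trend_date`), which the analysis never reads — it assigns
  its own synthetic dates, as the source did.
* **Copayments.** Log-normal around class-by-tier medians $10.60 / $11.81
  (ARB preferred / non-preferred) and $14.86 / $16.42 (IS), `sdlog`
  0.10. Multiplicative noise reproduces the right skew typical of cost
  data while leaving the medians at the published centers;
  dispersion 0 degenerates exactly to the centers.
* **Adherence.** A latent PDC target from the linear model: intercept
  0.894 (placing ARB PDC at ~74.6% at the non-preferred copayment),
  slope -0.08 per unit monthly copayment to the 1/4 power, -0.49 for
  inhaled steroids, +0.06 / +0.08 for the middle and upper income strata,
  -0.04 for more-than-daily dosing, prescriber random intercept SD 0.05,
  residual SD 0.06. The residual SD is deliberately small: the stated
  world is "PDC follows the linear model", and larger noise would clip
  substantially at the unit bounds, so the generated data would follow a
  censored law instead. Refills are emitted as 30-day supplies whose
  gaps realize the target to the day (the final fill is placed so exactly
  the residual days fall inside the window); partial adherence therefore
  comes from gaps, not short supplies, as in real claims.

What the generator does **not** emulate: generic tiers (the studied
classes were brand-only by design), coinsurance and pay-and-submit
plans, deductibles and out-of-pocket maxima, hospitalization or death
censoring, pediatric-specialty prescribing effects, and the U-shaped
dispersion of real-world PDC. A green recovery test therefore certifies
the estimators against the stated generating law — not against the messier
laws of real claims.

## Numerical and design choices

* **GEE.** No GEE implementation ships with the environment, so the
  package carries its own: Fisher scoring with the closed-form
  exchangeable inverse, moment estimators for dispersion and
  intra-cluster correlation, Liang-Zeger sandwich covariance, and Pan's
  QIC in its independence-quasi-likelihood form (model comparison only;
  other QIC variants differ by a constant trace term). It is verified
  against an independent reference implementation on a frozen fixture.
  Working weights are floored at `1e-10` so saturated fitted
  probabilities cannot produce indeterminate residuals, and design
  columns that are aliased or whose information vanishes (quasi-separated
  sparse cells — e.g. a tiny group-by-period cell that is all preferred
  tier) are dropped with a warning naming them.
* **Box-Cox selection** searches the grid {0, 1/4, 1/2, 1} (0 = log) by
  the RMSE of the transform-then-regress fit, optionally adjusted for
  covariates; without a response it maximizes the classical profile
  likelihood with its Jacobian. Ranking is scale-equivariant; ties break
  to the first grid entry. Within the synthetic world the within-cell
  copayment spread is too narrow to identify the exponent (the grid
  transforms are near-collinear there), so the pipeline pins the
  exponent at its generator-true 0.25 by default and `lambda = "select"`
  opts into data-driven selection; the selector itself is tested on data
  with a wide spread, where each grid exponent is recoverable.
* **Tier:copayment scale.** The model regresses the quarter-power
  copayment and back-transforms cell estimates, which is how skew-robust
  "median" cell copayments arise; `lambda = 1` gives the raw-dollar
  model. With zero generator dispersion both are exact.
* **Backward selection** removes, among removable terms (never a
  protected exposure term, never a main effect under a live
  interaction), the highest joint-Wald p-value above 0.05, but only if
  QIC (GEE) or ML-based AIC (mixed model) does not worsen; otherwise it
  tries the next candidate. Mixed models estimate by REML, with ML
  refits used only for AIC. Wald z inference is used for the mixed
  model's fixed effects.
* **Projections** round dollars to cents at the reporting edge and keep
  internal arithmetic unrounded. The external-benchmark copayment change
  is computed from the stated formula (`delta_p * (52 - 29)`), not
  hard-coded to a printed rounding of it. The benchmark elasticity
  projection treats the preferred-tier probability shift as the relative
  cost-sharing change, reproducing the published worked example; the
  source leaves the denominator of that relative change unstated, and
  all inputs are exposed so other readings can be computed.
* The pediatric-prescriber covariate is available behind
  `include_pediatric = TRUE` and off by default, matching the primary
  published model.

## A worked projection

```{r example, eval = FALSE}
library(fdslink)

dp <- net_probability_shift(1.9, 0.61)      # OR to probability shift
expected_copay_change(0.15, 10.60, 11.81)   # $0.18/month for ARB
expected_copay_change(0.08, 14.86, 16.42)   # $0.12/month for IS
100 * pdc_change_from_copay(-0.08, 11.18, 11.00)  # +0.06 points of PDC
100 * pdc_change_from_copay(-0.08, 11.81, 10.60)  # +0.40 points of PDC
elasticity_projection(0.60, 0.4, -0.15)     # +3.6 points, benchmark route
```

## Known limitations

The simulated tier draw is independent across a prescriber's claims given
the cell, so the exchangeable correlation it estimates is near zero; the
GEE's clustering machinery is exercised separately on correlated
fixtures. Synthetic control dates misclassify some non-adopter 2005
fills relative to the latent trend date — deliberately, since the placebo
construction in the source has the same property; the misclassification
shrinks the measured non-user secular trend slightly, so
difference-in-differences interaction recoveries run a few percent above
the generating odds ratio. PDC right-censoring
is flagged but not modeled. The three links are estimated separately, as
in the source; no joint uncertainty propagation into the chained
projection is attempted, and the projections are illustrative
compositions, not causal estimates.
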