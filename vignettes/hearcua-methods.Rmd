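---
title: "Cost–utility modelling of hearing-aid provision: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost–utility modelling of hearing-aid provision: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hearcua)
```

## The problem

Age-related hearing impairment is highly prevalent among older adults in
India, yet hearing-aid uptake is low. The policy question is whether public
provision of digital behind-the-ear (BTE) hearing aids — procured at the
government ceiling price of ₹8,000 per ear with a three-year warranty — is
good value for money, and what scaling provision nationally would cost.
`hearcua` implements the full evaluation pipeline: EQ-5D-5L utility scoring,
a short-horizon decision tree, a long-horizon cohort Markov model, ICER /
willingness-to-pay interpretation, and a budget-impact calculator.

## Utility measurement

Health states are EQ-5D-5L profiles: five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression), each at five levels;
`"11111"` is full health. A *value set* (tariff) converts a profile to a
utility anchored at 1 (full health) and 0 (dead), possibly negative. We
model tariffs additively: utility = intercept − Σ decrements over the five
(dimension, level) pairs, level 1 contributing 0. Any country tariff can be
supplied as a long CSV (`dimension, level, decrement` plus an intercept
row); on load the package checks that `"11111"` scores exactly to the
intercept, that level-1 decrements are zero and decrements are non-negative,
and warns (rather than errors) if a decrement decreases with worsening
level, since published value sets are occasionally non-monotone. Because
value-set coefficients are an external publication, the package ships only a
clearly-labelled synthetic *toy* tariff (intercept 1, floor 0.04) for tests
and examples; real analyses load the India EQ-5D-5L value set from file.
Utilities below zero are carried through all QALY arithmetic without
clamping.

Severity grading uses WHO better-ear thresholds with the moderate and
moderately-severe grades pooled: mild [20, 35), moderate [35, 65), severe
[65, ∞) dB. The ranges are half-open so the published integer ranges
(20–34, 35–64, ≥65) are matched exactly and non-integer thresholds resolve
to the higher grade at 35 and 65. Thresholds below 20 dB are below the
impairment range and raise an error rather than silently mapping to mild.

## The synthetic cohort generator

The pipeline was developed against a 2023 cross-sectional survey of 636
hearing-impaired adults aged 60+ in Odisha (276 hearing-aid users, 360
non-users) whose microdata are not redistributable. The generator therefore
emulates the survey's *published statistical structure*: exact cell counts
by arm × severity (users 36/122/118, non-users 153/131/76 across
mild/moderate/severe), the published cell mean utilities, and mean 3-year
cost components (₹111 + ₹4,257 for users, ₹131 + ₹1,452 for non-users).

Only cell means and counts are published, so the dispersion model is our
choice: utilities are drawn from a normal at the cell target mean with
standard deviation 0.15 — a typical EQ-5D within-group spread — truncated
to the utility bounds (default [−0.6, 1], spanning common value-set
floors), then **mean-recentred** per cell so the realised cell mean equals
its target to machine precision. Recentring makes downstream comparisons
exact rather than statistical; a `recentre = FALSE` flag gives raw draws
for stochastic realism. Costs are drawn from gamma distributions at the arm
means with coefficient of variation 0.3, guaranteeing non-negativity.

The published *overall* arm means (0.832 users, 0.601 non-users) are not
the count-weighted means of the published cell means (those give 0.843 and
0.599). The inconsistency is reproduced as given, not resolved: the default
`"cell"` calibration pins the cell means, and an `"overall"` calibration
mode adds one constant per arm so the overall arm means are pinned instead
— the mode used wherever the overall figures are the quantity of interest.
Because recentring shifts values after truncation, a shifted utility can
exceed the bounds by at most the shift (≈0.011 here); we accept this in
exchange for exactness. What passing tests show about real data is limited
accordingly: the generator reproduces first moments and design counts, not
the survey's true dispersion, covariance between utility and cost, or any
nonresponse structure.

All generation is seeded; a seed is mandatory, and identical (spec, seed)
pairs yield byte-identical cohorts.

## Costing

Direct medical costs have two components, applied on a fixed schedule:
consultation once over the horizon, diagnostic investigation/testing twice
in the first year and once in each subsequent year (so h + 1 applications
over h ≥ 1 years). The published 3-year aggregates are accepted directly as
per-person totals; unit-cost scheduling is available for scenario work.
Fitting cost adds `ears × price` to the direct medical total, giving
₹12,368 (unilateral) and ₹20,368 (bilateral) at the ceiling price.
Transportation and maintenance are supported as optional extra line items
defaulting to zero.

## The 3-year decision tree

The tree compares `no_aid` vs `unilateral` vs `bilateral` as strategies,
each carrying a per-person total cost and a mean utility. QALYs are
utility × accrual years, undiscounted inside the short tree — the published
tree arithmetic (16,751 / 1.617 = 10,359) is only consistent undiscounted.
The default accrual horizon is 7 years because both published overall
utility/QALY pairs divide to exactly 7.000 (5.824/0.832 and 4.207/0.601),
i.e. the remaining-life-expectancy assumption implicit in the source
figures; it is configurable, and severity-specific QALYs that do not divide
to a common horizon can be handled with per-strategy accrual inputs rather
than inferred. Strategy arm totals are direct inputs (defaults 11,420 /
19,420 / 2,669) because the published tree totals are not reconciled with
the fitting-cost table; the fitting costs (12,368 / 20,368) can be swapped
in via configuration. Probability-weighted sub-branches are supported, but
the default is a single branch of probability 1, matching the effectively
deterministic published tree.

With these inputs the package computes ΔQALY 1.617, Δcost ₹8,751 /
₹16,751, and ICERs of ₹5,412 (unilateral) and ₹10,359 (bilateral) per
QALY. The source prints ₹5,419 for the unilateral arm, which is not
reproducible from its own printed inputs (8,751 / 1.617 = 5,412.5) —
presumably rounding of unrounded internals; the package reports the
computed value.

## The 15-year Markov model

A three-state cohort model (mild, moderate, severe) with annual cycles over
15 years. Progression only: the transition matrix must be row-stochastic to
1e-12, entries in [0, 1], and upper-triangular (no improvement), so severe
occupancy is monotone non-decreasing and mild non-increasing. The trace
satisfies occupancy(t) = initial · mᵗ, verified in tests against an
independent matrix-power oracle. There is no death state — mortality and
competing risks are deliberately out of scope, as in the source model — so
occupancy is conserved exactly every cycle.

Arm-specific transition probabilities are **configuration inputs**: the
source figure's printed values could not be recovered from the text, so the
shipped defaults (`synthetic_transition_matrices()`) are clearly-labelled
synthetic placeholders in which users progress more slowly than non-users.
Absolute Markov totals consequently depend on the user's matrices and
cohort scaling and are not reproduced; the published incremental rows
(5,274,819/1,715 and 10,240,002/1,715) are taken as inputs where the
published ICERs (₹3,076 and ₹5,971 per QALY) are the target.

Numerical conventions, all configurable: discounting at 3%/year on both
costs and QALYs with cycle-end timing (cycle-t outcomes weighted
1/(1+r)^t, t = 1..15; `cycle_start` available); no half-cycle correction by
default (a flag enables averaging adjacent occupancies); the initial device
purchase at t = 0 undiscounted and replacements every 3 years while the
horizon has cycles left to serve (t = 3, 6, 9, 12 — a device bought at
t = 15 would serve no modelled time); re-evaluation cost (default 0, value
unpublished) charged per cycle to the expected newly-progressed fraction
1 − Σₛ occ(t−1, s)·m(s, s), the cohort-expectation reading of "re-evaluate
on status change"; cohort size a free scaling parameter defaulting to 1
(per-person results).

## ICERs, dominance and willingness to pay

ICER = Δcost/ΔQALY when the intervention is more effective and more costly.
All sign quadrants are mapped: dominant (no worse on both axes, better on
one), dominated (the reverse), tie (both zero), and the southwest quadrant
(cheaper and less effective), where the ratio is savings per QALY forgone
and is acceptable only when it meets or exceeds the threshold. The
willingness-to-pay benchmark is 1× India's per-capita GDP per QALY; no
rupee figure is hard-coded — the threshold is a required configuration
input, with ICER ≤ threshold counting as cost-effective (boundary
inclusive). Net monetary benefit (wtp × ΔQALY − Δcost) is provided as a
companion statistic; its sign provably agrees with the classification
whenever ΔQALY > 0. Reports round ICERs to whole rupees; full precision is
kept internally.

## Budget impact

Eligible persons = population × prevalence × need fraction, carried as a
real number throughout, with rounding (half-up, to integer persons and
whole crore; 1 crore = 10⁷) only at report time. Defaults mirror the
published scale-up block: 14.9 crore adults 60+, 10% prevalence, 4.7%
needing aids, a 35/65 unilateral/bilateral split, and the 3-year fitting
costs. These give 700,300 eligible persons (245,105 / 455,195 by category)
and category costs of ₹303 and ₹927 crore — totalling ₹1,230 crore over
3 years, ₹410 crore annually. Note that the source table prints fitting
counts of 24,510 / 45,520 alongside "4.7% (70,030)", which are a factor of
ten below what its own percentages and printed crore costs imply; the
package computes from the stated percentages, which reproduce the printed
costs exactly.

## Configuration and reporting

`load_config()` reads JSON or YAML, applies documented defaults, rejects
unknown keys, range-checks every numeric field, validates transition
matrices at load, and records the file's MD5 hash. `run_report()` executes
whichever stages the config enables and writes `report.json` plus per-stage
CSVs; the report embeds the seed, package version and config hash, and
identical (config, seed) runs produce byte-identical reports. The shipped
`inst/extdata/base_case.yaml` encodes the published tree inputs, the
synthetic Markov defaults and the budget-impact block.

```{r example}
cfg <- load_config(system.file("extdata", "base_case.yaml",
                               package = "hearcua"))
report <- run_report(cfg, tempdir())
report$tree$comparisons
```

## Problem sizes and limitations

All computations are desk-scale: the cohort is 636 records, the Markov
trace 16 × 3, and the property-style tests use 100 random matrices over 15
cycles — the full suite runs in well under a minute. Known limitations:
cross-sectional user/non-user utility differences may carry confounding
that no amount of modelling here removes; the Markov model has no mortality
and therefore overstates person-years at long horizons; probabilistic
sensitivity analysis is not implemented; and the shipped transition
matrices and toy tariff are synthetic placeholders that must be replaced
with study estimates for any substantive analysis.
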