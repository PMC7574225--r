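---
title: "A decision-tree cost-effectiveness model of sustained acoustic medicine for knee osteoarthritis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-effectiveness model of sustained acoustic medicine for knee osteoarthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatree)
```

## The question and the model

Patients with symptomatic knee osteoarthritis whose pain is severe enough to
keep them out of physical therapy (PT) are managed with a sequence of
conservative therapies: a pain-control modality first, then PT once pain
permits. `ceatree`'s bundled `knee_oa_2020` model compares two such pathways
over a six-month horizon:

* **SAM** — a wearable sustained acoustic medicine device (multi-hour,
  low-intensity home ultrasound) as the pain-control modality, followed by
  PT;
* **SOC** — the standard-of-care sequence (topical NSAIDs first-line, with
  steroid/hyaluronic-acid injections as escalation for non-responders),
  followed by PT.

Each arm is a chance node: with probability `p_*_success` the first-line
therapy controls pain enough to initiate PT; otherwise the patient escalates
(incurring `escalation_cost`) before eventually reaching PT. Terminals carry
a cost in USD and an effectiveness payoff expressed as a standardized effect
size on pain and function (dimensionless, Cohen's-d-like; values above 0.5
are conventionally regarded as clinically important). The horizon is six
months, so no discounting is applied and there is no QALY conversion — the
outcome stays in effect-size units throughout.

`rollback()` evaluates the tree as the probability-weighted sum of terminal
payoffs over all root-to-leaf paths. Strategies are fixed alternatives: the
decision root reports every strategy's expected payoff and never optimises.
The headline statistic is the incremental cost-effectiveness ratio,

$$\mathrm{ICER} = \frac{C_{\mathrm{SAM}} - C_{\mathrm{SOC}}}
                       {E_{\mathrm{SAM}} - E_{\mathrm{SOC}}},$$

in USD per unit of effect size, reported truncated toward zero to whole
dollars (see *Numerical choices*). A second comparison pair in the same
model file represents the later-stage pathway — responders continuing PT
with the device versus NSAIDs with PT.

```{r base-case}
model <- knee_oa_model()
evaluate_strategies(model)
incremental(model)
```

## Parameters, units and defaults

```{r parameters}
parameter_table(model$parameters)
```

Three kinds of numbers enter the model file, and the `note` column keeps
them honest:

1. **Published anchors** used at face value: the SAM device price
   (\$4,635, the average reimbursement price), the PT price per 15-minute
   session (\$41.80, used directly as the modelled payment rate; the
   separate `commercial_rate()` helper converts Medicare rates to
   commercial ones at the exact 1/0.75 ratio when a commercial-payer
   scenario is wanted), the 2–4 PT sessions per visit, and the per-strategy
   six-month totals the calibration targets.
2. **Reconstructed stage-level values** (flagged `reconstructed`): success
   probabilities, per-stage effect sizes, first-line and escalation costs,
   and the PT-utilization multipliers. The sources that would pin these
   down individually are not public, so they are documented placeholders
   chosen at clinically plausible magnitudes.
3. **Calibrated residuals** (flagged `calibrated`): one residual cost (and
   effect) constant per arm, solved by `calibrate_model()` so that the
   rollback reproduces the published totals *exactly*. Because the residual
   enters every terminal of its arm with coefficient 1, the rollback is
   linear in it and calibration is a one-step exact solve; a target below
   the arm's fixed stage costs is reported as infeasible rather than
   absorbed as a negative cost.

Two reconstruction choices deserve emphasis because they determine which
published numbers are independent validations and which are not:

* **The device cost enters the SAM arm at certainty.** Every SAM patient
  buys the device, so the incremental cost moves dollar-for-dollar with the
  device price and the break-even price is *base price − base incremental
  cost* = 4635 − 2359 = \$2,276. This identity holds regardless of the rest
  of the reconstruction, so reproducing the \$2,276 break-even is a genuine
  check of the calibrated totals.
* **The PT-utilization differential is reverse-engineered.** The cost
  difference responds to the PT session price at the rate of the *net*
  session differential between arms. That differential is fixed at
  2359/(88 − 41.80) ≈ 51.06 sessions — the unique value that puts the
  session-price break-even at \$88 — with the SOC arm the heavier PT user
  (clinically: slower pain control means a longer supervised-PT course).
  The expected base session count is set to 68.4 (≈ 2.85 sessions/visit
  over 24 weekly visits, inside the published 2–4 per visit), which is the
  value that places the session-count break-even at 144. The \$88 and
  144-session break-evens are therefore *consistency checks of the
  reconstruction*, not independent reproductions, and the package's tests
  treat them that way.

One erratum-level note: the published account of the base case prints an
effect difference factor of "0.53 less 0.39" in one place while printing
0.52 as the SAM effect everywhere else; 2359/0.13 reproduces the printed
\$18,146 ICER and 2359/0.14 does not, so the model uses 0.52. Similarly the
SOC total appears once as \$6,281 and once as \$6,282; the model uses
\$6,282, the value consistent with the \$2,276 break-even identity.

## Sensitivity analyses

`tornado()` ranks parameters by the swing of the cost difference over their
low/high range (others at base; ties broken alphabetically). The numeric
low/high ranges of the non-headline parameters are only known graphically
in the source material, so the ranges in the model file are the package's
own documented choices; with them, the ranking is led by the SAM device
price, the PT session price and the PT session count, in that order.

`find_threshold()` brackets a sign change of the cost difference and
bisects. Bisection is deliberate: the cost difference is monotone in every
cost-side parameter of this model family, the method needs no derivative,
and every evaluation is an exact rollback. A bracket without a sign change
is an explicit error, never a clamped answer.

```{r thresholds}
find_threshold(model, "sam_device_cost", c(0, 4635))
tornado(model)[1:3, ]
```

## Probabilistic sensitivity analysis

`run_psa()` draws every parameter from its distribution, rolls the tree
back once per strategy with vector-valued parameters, and summarizes the
incremental cloud: quadrant proportions on the cost-effectiveness plane
(x = incremental effect, y = incremental cost), the centroid, net monetary
benefit ($\mathrm{NMB}(\lambda)=\lambda\,\Delta E-\Delta C$) and the
acceptability curve. The reference analysis this emulates varied its
variables randomly 1000 times over their low/high ranges and reported the
share of iterations in the more-effective/more-costly (NE) quadrant and the
cloud's centroid; it is implemented here as Monte-Carlo sampling over the
decision tree — the description is of randomly varied variables and a
scatterplot, not of a health-state transition model, so no transition
matrix exists.

Distribution families are the package's choice, since the original
variable-by-variable distribution list is not public: triangular
(low, base, high) wherever a base value is a meaningful mode (costs,
counts, effect sizes), uniform (low, high) for the success probabilities.
Both use exactly the published or documented low/base/high anchors, and
sampling never clips: a distribution whose support violates a parameter's
role bounds (probabilities outside [0, 1], negative costs) is rejected
before any draw. Because the bundled triangulars are asymmetric, the PSA
centroid sits somewhat below the base-case increment and the NE share lands
around 90–94% rather than exactly the reference 84% — the reconstructed
spreads, not the engine, own those two numbers, which is why the tests pin
the centroid only under symmetric distributions (where the multilinear
rollback makes the expected increment equal the base case) and treat the NE
share as a qualitative check.

Reproducibility protocol: each parameter gets its own RNG sub-stream,
seeded from the root seed and the parameter's declaration index. Adding a
parameter to a model therefore leaves every other parameter's draws
untouched, and `(n, seed)` fully determines a `cea_psa` object.

## Numerical choices

* **ICER reporting truncates toward zero** to whole dollars (18146.15 →
  18146; 15576.67 → 15576); full precision is kept internally. Rounding
  half-up would report 15577 and is therefore not what the reference
  analysis did.
* **Branch probabilities must sum to 1 within 1e-9** (absolute) at every
  chance node, at every parameter assignment evaluated. Model files use
  explicit complements (`1 - p`), so sums are exact up to floating error;
  the tight tolerance catches genuinely inconsistent trees rather than
  rounding noise.
* **Bisection stops** when the cost difference is within \$0.01 of zero or
  the bracket has shrunk to 1e-6 of its initial width; thresholds are
  reported rounded to whole dollars.
* **Exact zeroes** in the dominance classification and quadrant summary get
  dedicated categories (`equal_cost`, `equal_effect`, `equal`; `zero_cost`,
  `zero_effect`, `origin`) instead of being folded into a quadrant:
  boundary assignment would be arbitrary, and for continuous distributions
  these categories are measure-zero anyway.
* **The expression language** for probabilities and payoffs allows only
  `+`, `-`, `*`, parentheses, numeric constants and parameter names —
  enough for linear cost accumulation (device price + session price ×
  session count), restrictive enough that model files cannot smuggle in
  arbitrary code and every payoff is multilinear in the parameters, which
  is what makes the calibration exact and the symmetric-PSA centroid
  property provable.

## What the synthetic generators emulate — and what they do not

`gen_tree()` produces random chance trees (simplex-sampled branch
probabilities via normalized exponential draws, the last branch set to one
minus the rest so sums are exact to 1e-12; uniform payoffs over
cost ∈ [0, 10000] USD and effect ∈ [0, 1], mirroring the knee-OA scale)
together with an expected value computed by an *independent* path
enumeration, never by the rollback under test. `gen_linear_model()` builds
two-strategy models whose cost difference is an explicit linear function,
giving closed-form break-even roots and tornado swings.

These generators exercise the engines, not the clinical problem: they
contain no cohort heterogeneity, no correlation between parameters, no
patient-level variation (the analysis is cohort-level throughout). Passing
tests on them shows the arithmetic is right — that rollback, bisection,
tornado and PSA compute what they claim on models of this family — not
that the reconstructed knee-OA inputs are the true ones.

Test and check problem sizes, chosen as comfortable margins for the
properties being tested: 100 random trees of depth 2–4 for the
rollback-vs-oracle identity, 20 random linear models each for the
threshold and tornado closed forms, 10,000 PSA iterations (±3 Monte-Carlo
standard errors) for the symmetric-centroid property, 1,000 random pairs
for the NMB/ICER sign equivalence.

## Known limitations

* Stage-level probabilities, costs and effects are reconstructions; only
  the arm totals, the device price, the PT pricing anchors and the
  break-evens are published. The calibration residuals make the gap
  explicit instead of hiding it in invented stage numbers.
* The PSA's distribution families and spreads are package choices; the NE
  share and centroid depend on them and should be read qualitatively.
* Opioid use, complication costs, regional price variation and
  correlated-parameter sampling are all out of scope, as in the reference
  analysis; expected value of perfect information is not computed.
* The patient population is under-65 (non-Medicare); the
  `commercial_rate()` conversion exists so Medicare-anchored inputs can be
  restated for commercial payers, but payment-rate scenario analysis beyond
  the PT-price threshold is left to the user.
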