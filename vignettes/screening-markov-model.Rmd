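---
title: "A Markov cohort model for the cost-effectiveness of DBT versus abbreviated breast MRI screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of DBT versus abbreviated breast MRI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenCEA)
```

## The decision problem

Women with heterogeneously or extremely dense breast tissue carry both an
elevated breast-cancer risk and a reduced chance that mammography will find a
tumor. Two technologies compete to close that gap in an intermediate-risk
screening program: digital breast tomosynthesis (DBT), a quasi-3D x-ray
technique that is cheap per examination but misses most cancers in dense
tissue (sensitivity 39.1%, specificity 97.4%), and abbreviated breast MRI
(AB-MRI), a shortened MR-mammography protocol that finds nearly all of them
(sensitivity 95.7%) at the price of more false alarms (specificity 86.7%)
and a higher examination cost.

`screenCEA` models a cohort of such women screened every two years from age
55 over a 30-year horizon, accruing costs (US-$, healthcare-system
perspective) and quality-adjusted life-years (QALYs), both discounted at 3%
per year. The decision quantity is the incremental cost-effectiveness ratio

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E}
 = \frac{C_{\text{AB-MRI}} - C_{\text{DBT}}}{E_{\text{AB-MRI}} - E_{\text{DBT}}},$$

judged against a willingness-to-pay (WTP) threshold of $100{,}000 per QALY,
equivalently via the net monetary benefit
$\mathrm{NMB}(\lambda) = \lambda\,\Delta E - \Delta C$.

## Per-round decision tree

Each attended screening round classifies every woman as true/false
positive/negative. A positive DBT goes straight to biopsy ($1,536). A
positive AB-MRI is first worked up with a full-protocol MR mammography
($314, specificity 94%); only MRM-confirmed findings proceed to biopsy, so a
false-positive AB-MRI episode costs $314 + 0.06 x $1,536 = $406.16 in
expectation, while a true positive costs $314 + $1,536. The confirmation is
assumed not to degrade detection of true cancers
(`sens_full_mrm_confirmation = 1`): the work-up cascade changes what a
positive costs, not the probability of detecting disease. The screening
examination itself is charged to every woman alive at the round, whichever
her state.

False positives also carry a one-off quality-of-life loss,
`u_fp_decrement`, reflecting the anxiety and unnecessary follow-up of a
false alarm. The default is 0.004 QALYs (about a day and a half of full
health) per episode -- a small value in the range used in mammography
cost-effectiveness work; it matters because AB-MRI produces roughly five
times as many false positives as DBT.

## Health states and natural history

The Markov state space comprises absence of cancer; undetected tumors in
three stages (< 1 cm, > 1 cm, advanced/regional); the corresponding
detected states; two post-treatment states (after simple and after
intensive therapy); and death. Undetected disease progresses on a
deterministic dwell clock: a new tumor stays below 1 cm for `dwell_small`
years (default 3), then above 1 cm for `dwell_large` years (default 4),
then becomes advanced. With two-yearly screening this wiring guarantees
that any tumor arising between rounds is still small at its first screening
opportunity -- the model's reading of "tumors detected within one screening
interval are successfully treated" -- while repeatedly missed tumors
surface one stage later each round.

Detection moves a tumor to the detected state of its current stage for one
cycle, during which the one-off treatment cost falls ($60,637 / $82,121 /
$129,387 by stage) together with the positive work-up. A tumor detected
above 1 cm is escalated to the advanced treatment pathway (advanced cost,
utility and mortality) with probability
$p_{N+} + (1 - p_{N+})(1 - p_{R0}) = 0.40 + 0.60 \times 0.10 = 0.46$,
combining nodal involvement and incomplete first resection. Detected states
then empty into the post-treatment states: simple therapy after a small
tumor (utility 0.99), intensive therapy otherwise (utility 0.95).

Disease enters the model two ways: a pre-test prevalence of 1.59% forms the
initial undetected-small mass at the first (cycle-0) screen, and an annual
incidence of 0.40% moves healthy survivors into the undetected-small state
every later cycle.

## Mortality

Three hazards act as independent competing risks, combined per cycle as
$p_{\text{die}} = 1 - (1 - q_{\text{bg}})(1 - q_{\text{tumor}})$:

* background (other-cause) mortality $q_{\text{bg}}$ from the bundled
  female life table;
* undetected-tumor mortality, 10% cumulative over 10 years, converted by
  the constant-hazard rule `annualize_risk(0.10, 10)` = 0.0105/year;
* stage-specific mortality after detection (0.11% / 0.78% / 1.81% per year
  for small / large / advanced).

The input table treats the background risk as a single "age-adjusted"
yearly quantity, and the model's published cost structure (the exactly
linear dependence of cumulative cost on the exam price, with slope ~9.64
discounted screens) is consistent only with a constant annual background
risk close to the life-table value at the entry age. The default mode
`background_mortality = "entry_age_constant"` therefore applies
$q_x(\text{start age})$ throughout; a fully age-specific mode
(`"age_specific"`) is implemented and tested, and lowers survival -- and
with it discounted screens, QALYs and costs -- noticeably over a 30-year
horizon.

The bundled life table (`life_table_female_2017_synthetic.csv`) is a
log-linear single-year interpolation of published five-year female death
probabilities for US women, ages 40-100; it is a synthetic reconstruction,
not the original vital-statistics file. A parametric Gompertz generator
(`gompertz_life_table()`) provides a fully synthetic alternative.

The post-treatment mortality cut-off `post_mort_years` (default 0) stops
the stage-specific hazard after the detection year: patients treated in
this model are treated curatively, and their subsequent survival reverts to
background. Setting it larger (or `Inf`) lets the stage hazard persist.

## Accrual conventions

One cycle is one year. Within a cycle the engine applies, in order:
screening (if due), QALY accrual, death, onset, progression, and
detected-to-post transitions. Two conventions matter:

* **No half-cycle correction.** Each woman accrues the full-year utility of
  the state she occupies after the screening event, with deaths taking
  effect at the end of the cycle. Detected women therefore accrue the
  detected-state utility (0.87 / 0.74 / 0.62) for exactly the detection
  year, and the degenerate no-disease/no-death model attains the 30-cycle
  discounted annuity bound $\sum_{t=0}^{29} 1.03^{-t} = 20.1885$ QALYs
  exactly.
* **Death before onset.** Background death is applied before new disease
  onset within a cycle, so onset acts on survivors; the alternative order
  differs only at order $q \cdot \text{incidence}$.

Costs accrue in the cycle of the event (exam and work-up at the screen,
treatment once at detection, nothing annually otherwise) and are discounted
with the same $1.03^{-t}$ factors, cycle 0 undiscounted.

## Calibration

The published account of this model fixes all rate, cost and utility
inputs but leaves the natural-history wiring open: how long tumors dwell
per stage, how long tumor mortality persists after treatment, and the size
of the false-positive QALY decrement. These are the package's calibration
knobs, fixed once against the published base-case table and price
thresholds and not varied thereafter:

| knob | value | role |
|---|---|---|
| `dwell_small` | 3 y | fraction of DBT-missed tumors still small at the next round |
| `dwell_large` | 4 y | split of late detections between large and advanced |
| `post_mort_years` | 0 y | long-run survival of treated patients |
| `u_fp_decrement` | 0.004 QALY | weighs AB-MRI's false-positive excess against its detection gain |

With these values the model reproduces the published incremental results
closely: incremental cost within ~2%, incremental QALYs within ~1.5%, the
ICER within ~1%, both examination-price thresholds within a few dollars,
and the cost-grid slopes within 1%.

The *absolute* cumulative cost levels, however, come out ~12% below the
published ones, and provably must under this structure: with a pre-test
prevalence of 1.59% and an annual incidence of 0.40%, the discounted mass
of treated cancers cannot exceed about 0.084 per woman, which caps the
AB-MRI cumulative cost near $8,700 -- below the published $9,505. The
published levels imply roughly a quarter more treated-cancer flow than the
printed epidemiological inputs generate; since every incremental and
decision-relevant quantity reproduces, the difference is carried by both
strategies alike (plausibly an additional cost stream or disease flow in
the original implementation that its publication does not parameterize).
The corresponding two assertions in the acceptance test file are left
failing by design rather than silently loosened.

## Sensitivity analyses

**One-way (tornado).** Each distribution-tagged input is varied +/-20%
(probabilities and utilities capped at 1; the AB-MRI exam price over the
published scenario span $180-350; the start age +/-2 years) with everything
else at base, and the ICER excursion is recorded. Under these uniform
ranges the AB-MRI exam price and the DBT/AB-MRI specificities dominate;
incidence sits in the upper half. A +/-20% swing is arguably generous for
utilities near 1, which inflates their apparent influence -- ranges are
fully configurable per parameter.

**Probabilistic.** Every uncertain parameter carries a distribution family
from the input table -- beta for probabilities and utilities, gamma for
costs, normal for the starting age -- parameterized by method of moments
around the base mean. The dispersions are not published; the default policy
is a coefficient of variation of 0.10 for every beta/gamma parameter and an
SD of 2 years for age. Draws are independent (no correlation structure is
published). Two consequences are worth knowing:

* for means very close to 1 (e.g. the 0.99 post-treatment utility) a CV of
  0.10 produces a strongly left-skewed beta -- the moment match is exact
  but the shape is extreme;
* the model is nonlinear in its parameters, so the PSA mean of
  $\Delta C$ sits a few percent below the base-case value (a Jensen gap,
  not a bug); it becomes statistically resolvable only at very large
  iteration counts.

The cost-effectiveness acceptability curve is the fraction of draws with
non-negative NMB per WTP value. Its level at $100k/QALY depends directly on
the unpublished dispersion policy: with CV = 0.10 the model yields ~93%,
against a published 83.2%; the published value cannot be pinned without the
original spread choices, so the package treats it as a qualitative check
(the acceptance test asserts a broad 60-99.5% band).

## The microsimulation oracle

`simulate_individuals()` realizes the same engine object -- identical
per-cycle probabilities, event order, prices and utilities -- as individual
Bernoulli draws for `n` women, rather than propagating expectations. It is
the package's synthetic-data generator and brute-force validator: for any
parameterization, mean discounted cost and QALYs must agree with the
cohort totals within Monte Carlo error, and empirical per-cycle state
frequencies with the cohort occupancies. Because both consumers share one
transition implementation, this test exercises the propagation arithmetic,
not a second model that could drift. What passing it does **not** show is
anything about real screening data: the generator emulates the model's own
probabilistic structure (no adherence variation, no interval symptomatic
detection, no tumor-growth heterogeneity), so agreement validates internal
consistency, not external calibration.

Validation scale: the bundled analysis and acceptance checks use 50,000
women per strategy, which puts the standard error near $70 on a ~$8,000
cost total and 0.015 on a ~19-QALY total.

## Numerical choices and degenerate inputs

* Threshold prices are solved in closed form on the affine relation
  $\Delta C(p) = \Delta C(p_0) + s\,(p - p_0)$, where the slope $s$ is the
  discounted attended-screen count, then verified by a full cohort re-run
  (residual < $0.01 for cost neutrality, < $1/QALY at the WTP threshold).
  The affinity itself is asserted by a three-point collinearity check.
* ICERs are always computed on unrounded $\Delta C, \Delta E$; dominance
  (cost-saving) cells report a label, not a ratio.
* Beta moment-matching fails when the requested variance exceeds
  $m(1-m)$; PSA re-draws on failure and errors if more than 1% of draws
  are infeasible.
* A screening interval longer than the horizon yields exactly one
  (prevalence) round; `annualize_risk(1, y)` is rejected as an infinite
  hazard; occupancy vectors must be non-negative and sum to one within
  1e-8 or the transition errors.
* Ages above the life-table maximum clamp to the last row, keeping the
  engine total for long horizons.

## Known limitations

* No interval (symptomatic) detection between screening rounds: a missed
  tumor waits for the next round, which overstates the detection delay of
  low-sensitivity strategies in reality.
* Tumor stage is the only disease attribute: no DCIS/invasive split, no
  growth-rate heterogeneity, no radiation-induced risk.
* Attendance is 100% and screening continues to the end of the horizon;
  there is no stopping age.
* Costs are a single payer perspective in constant US-$ with no inflation
  or currency machinery.
* The absolute cost levels are not calibrated (see above); analyses should
  rely on incremental quantities, which is also how the decision criteria
  are defined.
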