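# screenCEA

Model-based cost-effectiveness analysis of two-yearly breast-cancer
screening with **abbreviated breast MRI (AB-MRI)** versus **digital breast
tomosynthesis (DBT)** in women at intermediate risk due to dense breast
tissue — for health-economics researchers and modellers who want the full
analysis (base case, threshold, tornado, PSA/CEAC) as tested, scriptable R
code rather than a point-and-click decision tree.

The core is a Markov cohort state-transition model: women move annually
between absence of cancer, undetected tumor stages (< 1 cm, > 1 cm,
advanced), detected/treatment states, post-treatment states and death,
while a per-round decision tree (sensitivity/specificity, biopsy and
full-MRM work-up cascades) generates detections and false alarms at every
screen. Discounted costs *C* and quality-adjusted life-years *E* accumulate
over a 30-year horizon (3%/year), and strategies are compared by the
incremental cost-effectiveness ratio

```
ICER = ΔC / ΔE = (C_ABMRI − C_DBT) / (E_ABMRI − E_DBT)
```

against a willingness-to-pay threshold λ = $100,000/QALY (equivalently, net
monetary benefit NMB = λ·ΔE − ΔC). An individual-level microsimulation of
the identical transition logic serves as a brute-force validation oracle.

## Worked example

```r
library(screenCEA)

params <- default_parameters()   # published base-case inputs
bc <- base_case(params)
print(bc$table, digits = 7)
#  strategy cum_cost inc_cost cum_qaly   inc_qaly     icer
#       DBT 7748.107       NA 19.06531         NA       NA
#    AB_MRI 8438.938 690.8302 19.09882 0.03351094 20615.06

solve_price_threshold(params, mode = "cost_saving")  # 242.96
solve_price_threshold(params, mode = "wtp")          # 587.56
```

Read: screening with AB-MRI costs $690.83 more per woman over 30 years and
gains 0.0335 QALYs, an ICER of about $20,600 per QALY — cost-effective well
below the $100k threshold. If the price of an AB-MRI examination fell below
$242.96 the strategy would be outright cost-saving versus DBT; it remains
cost-effective up to an exam price of $587.56.

The full analysis lives in numbered scripts under `analysis/` (run from the
repository root; outputs land in `results/`):

| script | writes |
|---|---|
| `01_base_case.R` | base-case table, per-cycle trajectories |
| `02_price_thresholds.R` | cost-saving and WTP price thresholds |
| `03_cost_grid.R` | cumulative-cost/ICER grid over exam prices |
| `04_tornado.R` | one-way sensitivity (tornado) table |
| `05_psa.R` | 30,000-iteration PSA scatter + CEAC (a few minutes) |
| `06_microsim_validation.R` | cohort vs 50,000-woman microsimulation |

Parameters are fully overridable from YAML or code, e.g.
`load_parameters("my.yaml", overrides = list("cost_exam[AB_MRI]" = 250))`.

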