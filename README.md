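# woundcea

Decision-analytic cost-effectiveness analysis of chronic-wound dressing
strategies, for health economists and HTA analysts. The package implements
a two-strategy, two-outcome decision tree from a payer perspective over a
fixed horizon, and everything around it: base-case rollback, incremental
analysis with dominance classification, one-way sensitivity analysis with
tornado ranking, and probabilistic sensitivity analysis (PSA) with
cost-effectiveness plane and acceptability curves. A built-in scenario
compares hyaluronic-acid (HA) dressings with silver-containing dressings
under German statutory health insurance tariffs in 2021 Euro over 12
weeks.

## The model

Each strategy arm is costed as

```
cost = horizon_weeks × units_per_week × (unit_price + change_tariff)
```

(each dressing unit applied bills one home-care dressing change), and
valued by its probability of complete healing at the end of the horizon.
For intervention *i* vs comparator *c*:

- ΔC = C_i − C_c, ΔE = E_i − E_c, ICER = ΔC / ΔE (from unrounded inputs)
- dominance: *i* dominant iff ΔC ≤ 0 and ΔE ≥ 0 with one strict
- net monetary benefit at willingness to pay λ: NMB = λ·E − C; the CEAC
  reports the share of Monte-Carlo iterations in which each strategy has
  the higher NMB (ties split ½/½)

PSA distributions: gamma (scale, shape) for prices and the shared
dressing-change tariff, binomial for units per week, beta for healing
rates. The built-in tariff gamma is moment-matched to its baseline mean
by default because the published parameters are internally inconsistent;
see the methods vignette (`vignettes/wound-dressing-cea.Rmd`).

## Worked example

```r
library(woundcea)

scn <- paper_scenario()          # built-in HA vs silver scenario
base_case(scn)
#> Base-case results (costs in 2021 Euro)
#>   HA         cost   749.80   healing rate 0.6068
#>   Silver     cost   883.05   healing rate 0.5962
#>   incremental cost -133.25, incremental healing 0.0106
#>   ICER -12570.57   [intervention_dominant]
```

HA heals slightly more patients (60.68% vs 59.62%) at lower cost
(749.80 vs 883.05 Euro), so it dominates; the negative ICER
(−12,570.57 Euro per additional healed patient) is reported but the
quadrant label carries the decision.

```r
tornado_table(run_owsa(scn))[1:2, c("parameter", "width")]
#>               parameter     width
#> 1 units_per_week_Silver 1324.5732
#> 2     units_per_week_HA  374.9004
```

The tornado ranking shows results are driven by the number of dressings
used per week, not by unit prices (the widths are incremental net
monetary benefit ranges at λ = 0, in Euro).

```r
psa <- run_psa(scn, n = 10000, seed = 1)
cc <- ceac(psa)
cc[cc$wtp %in% c(0, 10000), ]
#>       wtp p_intervention p_comparator
#> 1       0         0.6941       0.3059
#> 101 10000         0.5778       0.4222
```

HA is the cost-effective choice in ~69% of iterations at a willingness
to pay of 0 Euro, levelling near 58–60% by λ = 10,000 — the HA curve
stays above the silver curve at every grid point.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/wound-cea ceac --seed 1 --iterations 10000 --outdir out/
```

writing `base_case.csv` / `owsa.csv` / `psa_samples.csv` /
`ce_plane.csv` / `ceac.csv` plus a `manifest.json` that fully determines
the outputs. Scenario configurations are JSON documents (schema: top-level
`strategies` [array of 2], `change_tariff`, `horizon_weeks`, `currency`;
each parameter has `baseline`, `owsa: {low, high}` or `owsa: {pct: 5}`,
and `dist: {family, params}`); `write_scenario()` / `load_scenario()`
round-trip them exactly.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the full PSA pipeline from scratch on the built-in scenario
(10,000 Monte-Carlo iterations, moment-matched tariff mode) and writes
the probability (in percent) that the HA strategy is cost-effective at
willingness-to-pay 0 and 10,000 Euro, as computed from the freshly
simulated acceptability curve.
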