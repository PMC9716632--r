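---
title: "Decision-analytic cost-effectiveness of wound dressing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-analytic cost-effectiveness of wound dressing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundcea)
```

## The model

`woundcea` evaluates two chronic-wound dressing strategies with a
two-strategy, two-outcome decision tree from a payer (German statutory
health insurance) perspective. A decision node chooses the strategy; per
strategy a chance node splits patients into *healed* and *not healed* at
the end of a fixed horizon (default 12 weeks). The effectiveness endpoint
is the probability of complete healing at the horizon; the cost endpoint
is the expected dressing-related cost over the horizon.

Two modelling assumptions make the rollback closed-form:

1. **Cost is outcome-independent.** Dressings and dressing changes accrue
   for the full horizon in both the healed and the unhealed branch. The
   model deliberately ignores when within the horizon healing occurs; this
   tends to overestimate the cost of a faster-healing strategy, a
   limitation shared with comparable evaluations.
2. **Each dressing unit applied is one billed dressing change.** Weekly
   cost is therefore

   $$c_{\text{week}} = u \cdot (p + t),$$

   where $u$ is units per week, $p$ the dressing unit price and $t$ the
   home-care tariff per change, and the horizon cost is
   $C = h \cdot c_{\text{week}}$ with $h$ the horizon in weeks. This is
   the unique reading of the published inputs that reproduces the
   published arm costs ($12 \times 2 \times (19.075 + 12.1667) = 749.80$
   and $12 \times 2 \times (24.627 + 12.1667) = 883.05$ Euro).

No discounting is applied: the horizon is under one year.

Incremental analysis reports $\Delta C$, $\Delta E$, the ICER
$\Delta C / \Delta E$ and a dominance label. The ICER is computed from
*unrounded* costs and effects — the published $-12{,}570.57$ only
reproduces that way ($-133.248 / 0.0106$); dividing the rounded
$-133.25$ gives $-12{,}570.75$. A negative ICER is reported but not
interpreted; the dominance quadrant carries the decision. Exact zero
deltas resolve toward dominance when the other delta is favourable, and
to `equivalent` when both vanish.

```{r base-case}
base_case(paper_scenario())
```

## Parameters and the built-in scenario

Every model input is a `parameter_spec()`: a baseline, a deterministic
sensitivity (OWSA) range bracketing it, and a PSA distribution. The
built-in `paper_scenario()` carries the published registry verbatim:
gamma-distributed prices (support $> 0$), binomially distributed units
per week (only whole units are billable), beta-distributed healing
probabilities, and one shared dressing-change tariff. Percentage OWSA
ranges on prices are materialised to absolute bounds at load time so all
downstream code treats ranges uniformly.

Gamma parameters are read as *(scale $\theta$, shape $\kappa$)*; this
convention is validated by the price rows, whose means
$\kappa\theta$ ($0.0477 \times 400 = 19.08$ and
$0.0616 \times 400 = 24.64$) recover the price baselines.

**The tariff gamma repair.** The published tariff gamma
$(\theta, \kappa) = (0.5264,\ 213.55)$ has mean $112.4$ Euro under that
same convention — inconsistent with the tariff's own baseline of
$12.1667$ Euro under *any* parameter ordering, an apparent misprint. The
default `tariff_gamma = "moment_matched"` keeps the printed scale
(preserving the dispersion per unit mean) and solves the shape so the
mean equals the baseline ($\kappa = 12.1667 / 0.5264 \approx 23.113$);
`"as_printed"` exposes the literal parameters. Both modes are recorded in
the run manifest. Acceptance-level results quoted anywhere in this
package use the moment-matched mode.

Two further registry quirks are kept as printed rather than "repaired":
the binomial PSA means ($8 \times 0.18 = 1.44$, $8 \times 0.23 = 1.84$)
do not equal the baseline 2 units/week, and the comparator healing-rate
baseline 0.5962 differs from the pooled-count derivation
$148/254 = 0.5827$ that `healing_rate_from_counts()` documents. The
built-in scenario is the published analysis, not an idealisation of it.

## One-way sensitivity analysis

`run_owsa()` re-evaluates the model once per parameter at its low and
high bound, all others at baseline. The tornado outcome metric is the
**incremental net monetary benefit** of the intervention at a reference
willingness to pay $\lambda$ (default 0):
$\mathrm{iNMB}(\lambda) = \lambda\,\Delta E - \Delta C$, which at
$\lambda = 0$ equals $-\Delta C$. The ICER was rejected as a tornado
metric by design: the wide healing-rate ranges can flip the sign of
$\Delta E$ and make the ratio explode, while the iNMB stays bounded and
monotone in every cost parameter. Two consequences users should expect
at the default $\lambda = 0$: healing-rate bars have zero width (effects
do not enter costs), and the shared tariff bar has zero width whenever
both arms use the same baseline units per week (it cancels out of
$\Delta C$ analytically).

```{r owsa}
tornado_table(run_owsa(paper_scenario()))
```

## Probabilistic sensitivity analysis

`run_psa()` draws every parameter independently from its PSA
distribution — per iteration: intervention price, units, healing rate;
comparator price, units, healing rate; one *shared* tariff draw applied
to both arms — and revalues the tree. Draws are generated vectorised per
parameter in that documented order from a single seeded generator;
identical `(scenario, n, seed)` gives identical output, which the suite
asserts byte-for-byte on the CSV exports. No correlation structure is
imposed (none is specified for the source scenario), and binomial draws
of 0 units are retained as zero-cost weeks — excluding them would bias
the sampled mean away from $np$.

The acceptability curve `ceac()` reports, per willingness-to-pay value,
the share of iterations in which each strategy has the higher net
monetary benefit $\lambda E - C$. Exact NMB ties — which occur with
positive probability at $\lambda = 0$ when both arms draw zero units —
are split half/half, keeping the two curves exactly complementary. The
default grid is 0 to 10,000 Euro in steps of 100.

```{r psa}
psa <- run_psa(paper_scenario(), n = 10000, seed = 1)
cc <- ceac(psa)
cc[cc$wtp %in% c(0, 5000, 10000), ]
```

## Synthetic scenarios and what a green test establishes

`generate_scenario()` emulates scenarios of the same shape with known
ground truth: baselines drawn uniformly from realistic ranges (unit
prices 5–50 Euro, 1–4 units per week, healing rates 0.05–0.95, tariffs
5–20 Euro — spanning the published values by a comfortable margin), OWSA
bounds bracketing each baseline, and PSA distributions *moment-matched*
to the baselines (gamma with shape 400 relative scale for prices,
binomial over 8 trials centred on the units baseline, beta with
concentration 5 for rates). Moment-matching is what the built-in
scenario deliberately does not do; the generator needs it so that the
closed-form oracle

$$\mathbb{E}[C] = h \cdot \mathbb{E}[U]\,(\mathbb{E}[P] + \mathbb{E}[T])$$

(exact by independence) equals the baseline rollback, making parameter
recovery and convergence testable without simulation on the oracle side.
`degenerate_scenario()` builds all-point-mass scenarios hitting exact
target valuations; their acceptability curves are deterministically
1 / 0 / 0.5 under strict dominance / its mirror / exact equivalence, the
brute-force anchor for the CEAC code path.

Generated scenarios emulate the *structure* of real dressing-choice
problems, not their clinical content: parameters are mutually
independent, distributions are unimodal and centred on truth, and there
is no patient-level heterogeneity, time-to-healing dynamics or
adverse-event cost. A green test therefore establishes that the
arithmetic, sampling and bookkeeping are correct — not that the model
generalises beyond its stated assumptions.

## Numerical choices

* Full double precision is kept internally everywhere; rounding (2
  decimals for costs, 4 for rates) happens only in report columns and
  `print()` methods.
* CSV exports are locale-independent (period decimal separator, comma
  delimiter, UTF-8) and write numerics as `%.17g`, so re-reading a CSV
  and recomputing derived columns reproduces them bit-for-bit.
* `ceac()` classifies an iteration by the sign of
  $\lambda\,\Delta E - \Delta C$; ties are exact floating-point zeros,
  which arise from point-mass scenarios and zero-unit draws, not from
  tolerance thresholds.
* Scenario round-trips through JSON are exact for integers and labels
  and to 12 significant digits for reals (serialisation uses full
  precision; the tolerance only cushions decimal-to-binary parsing).
* Degenerate inputs: zero units per week are valid (zero cost); a
  healing rate override outside $[0,1]$ is an error; an empty OWSA table
  or empty willingness-to-pay grid is an error rather than an empty
  result.

## Known limitations

Only two strategies and the fixed two-branch tree shape are supported —
no efficiency frontiers, extended dominance, Markov structure, per-week
healing dynamics or QALY/cost-utility extension. The expected value of
perfect information is out of scope, as is any correlated-parameter
sampling. Plot rendering is intentionally absent: the exported tables
(tornado table, CE-plane points, CEAC curve) are the load-bearing
output, and any plotting layer can be built on them.
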