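---
title: "Methods: greenhouse-gas accounting for synthetic N fertiliser supply chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: greenhouse-gas accounting for synthetic N fertiliser supply chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertghg)
options(fertghg.quiet = TRUE)
```

## The accounting model

`fertghg` estimates the greenhouse-gas footprint of synthetic nitrogen
fertiliser per country as the sum of six components, all in tonnes of
CO₂-equivalent:

1. **Manufacturing** — consumption-based: the tonnes of each of eight
   product groups (anhydrous ammonia, AN, AS, CAN, urea, UAN, AP, NPK)
   consumed nationally, times the factory-gate EF (tCO₂e per tonne product)
   of the region of production.
2. **Transport** — the same tonnages split over regions of origin by a
   sourcing mix, times (origin, destination, product) transport EFs.
3. **Direct soil N₂O** — total national N consumption times a direct EF
   (kg N₂O-N per kg N), converted via 44/28 (N₂O-N → N₂O) and the N₂O
   GWP-100.
4. **Indirect, volatilisation** — N × FRAC_GASF × EF₄, same conversion.
5. **Indirect, leaching** — N × FRAC_LEACH × EF₅, same conversion.
6. **Urea hydrolysis** — tonnes of urea-equivalent product times an EF in
   tCO₂-C per tonne, converted via 44/12.

The national total is the exact component sum; regions and the globe are
component-wise sums over countries. Two structural assumptions are inherited
from the inventory tradition this follows: emissions are **linear** in
activity (no rate-dependent EF response), and national activity data carry
**no uncertainty** (only EFs do), because consumption statistics come without
error models.

Key conventions: 44/28 and 44/12 are stoichiometric constants and not
configurable; the GWP default is 265 (configurable, e.g. 298 or 273 for
other assessment vintages). The N not covered by the eight product groups
(about 4% of world consumption in real market-mix data) is included in the
field components, which use total N, but excluded from manufacturing and
transport, for which no product information exists — so production and trade
emissions are slightly underestimated by construction.

## Direct emission factors

Three scheme families are supported by `get_direct_ef()`:

* `ipcc_tier1`: 0.010 ± 0.009, truncated to [0.001, 0.018], normal.
* `ipcc_wetdry`: wet 0.016 ± 0.003 on [0.013, 0.019]; dry 0.005 ± 0.006 on
  [−0.001, 0.011], normal. The dry minimum is negative: soils can be a net
  N₂O sink, and plot-level EFs are therefore never truncated at zero.
* `empirical_*`: estimated from paired-plot data. The plot-level EF is the
  treated-minus-control flux difference divided by N applied — the division
  makes the quantity dimensionless and commensurable with every scheme above
  and with the accounting equations. Country EFs are plot means with the
  sample sd (n−1); regional EFs weight country means by plot counts (which
  equals the pooled plot mean, so the regional sd is computed from the
  pooled plot EFs, preserving within-country dispersion); the global EF
  weights regional means by the number of countries *with data* per region
  (not all countries of the region — an open reading; the countries-with-data
  choice avoids giving sparsely measured regions weight they have no data to
  support). Empirical EFs are modelled lognormal; a non-positive empirical
  mean cannot be moment-matched to a lognormal and falls back to a normal.

Filtering before estimation keeps only synthetic-fertiliser records with a
valid control pair, positive N rate and finite fluxes, and drops exact
duplicates; each removal reason is counted and logged. Negative plot EFs are
retained — truncation would bias country means upward.

## Indirect factors

The volatilisation and leaching factors are applied per country by its
wet/dry climate class (assigned by cropland majority; ties resolve to wet,
the conservative, higher-EF choice). The shipped defaults — FRAC_GASF 0.11,
EF₄ 0.014 (wet) / 0.005 (dry), FRAC_LEACH 0.24 (wet) / 0 (dry), EF₅ 0.011 —
are explicit stand-ins labelled `IPCC-2019-default` in provenance and logs,
and every one is overridable by config. The FRAC terms carry sd 0.05
(normal); EF₄/EF₅ sds are set from the published IPCC ranges (roughly a
quarter of the range width). The dry-climate leaching fraction is a
structural zero and carries sd 0: giving it the generic 0.05 sd under [0, 1]
truncation would manufacture a spurious positive leaching flux for dry
countries whose printed value is exactly zero.

## Monte Carlo propagation

`propagate_uncertainty()` samples every EF `n` times (default 5,000, the
conventional size for inventory uncertainty analysis) and evaluates the
accounting once per draw. Numerical choices:

* **Correlation structure.** One draw per EF per iteration, shared by every
  country using that EF; distinct EFs are independent. The alternative —
  independent draws per country — would average national errors away and
  collapse aggregate CVs toward zero, which contradicts how a shared EF
  table propagates error: if the urea EF is wrong, it is wrong everywhere at
  once.
* **Truncation by rejection.** Draws outside [min, max] are redrawn, not
  clamped; clamping would put probability atoms on the bounds and bias
  means.
* **Lognormal parameterisation.** Moment-matched on the natural scale
  (σ² = log(1 + cv²), μ = log(mean) − σ²/2), because EF tables state
  natural-scale means and sds.
* **Zero-sd countries.** A country whose empirical EF rests on a single plot
  has sd 0; its regional sd is substituted with a warning, since zero
  variance would understate national uncertainty.
* Summaries are sample means/sds over draws (not analytic), with the CV
  reported as 100·sd/mean and missing where the mean is 0.

The deterministic engine and the Monte Carlo share a single evaluation path:
the chain is compiled once into coefficient structures over an indexed EF
vector, evaluated at the means (deterministic) or at the draw matrix (MC).
This guarantees per-draw totals equal per-draw component sums and that
zero-uncertainty propagation reproduces the deterministic result; the test
suite checks the engine itself against an independently hand-coded
single-expression implementation of the chain on random small inventories.

## Indicators and trends

Carbon intensity (tCO₂e/tN), per-capita footprint (kg CO₂e/person),
fertilisation rate (kg N/ha) and component shares are plain ratios with
guarded denominators. Growth rates are two-point percent changes with a
configurable lag (default 1 year — the published rate figures are annual
even where the formula is named for a decade); moving averages are centred,
with incomplete edge windows dropped, and the smooth-then-rate order is used
where both are applied (the alternative order is not distinguishable from
published material; smoothing first gives the stabler series). Missing years
are never gap-filled; a rate spanning a gap is reported missing.

## What the synthetic generator emulates — and what it does not

`world_spec()` defines a 9-region × 5-country world consuming 100 Mt N
(matching the order of magnitude of real global consumption), with:

* lognormal country consumption rescaled to the world total exactly;
* per-region Dirichlet product mixes at 96% coverage, applied uniformly to
  member countries (regional mixes standing in for national ones);
* regional true direct EFs spanning 0.003–0.024 — low in Africa and the
  Russian Commonwealth, high in the Americas, echoing the reported spread of
  empirical regional estimates — with lognormal country-level variation
  (log-sd 0.3, mean-preserving);
* paired plots with multiplicative lognormal plot noise (log-sd 1.0,
  mean-preserving, so the estimator is unbiased; this puts the plot-level
  CV above 100%, the right order for field N₂O measurements), an
  independent positive control-plot baseline (mean 0.5 kg N₂O-N/ha) so the
  subtraction in the EF formula is genuinely exercised, N rates uniform on
  50–250 kg N/ha, and 3× plot oversampling in North America and Europe to
  mimic the documented data bias;
* manufacturing EFs with sd = 25% of the mean (lognormal) and transport EFs
  with sd = 50% (normal, truncated at zero), the uncertainty rules attached
  to the restricted EF tables this generator stands in for;
* a sourcing mix with 79% intra-regional supply, matching the reported share
  of fertiliser consumed in its region of production;
* trend series with growth decaying from 15%/yr to 2.5%/yr (timescale 15
  years), the observed historical pattern of fertiliser-use growth.

All draws descend from one master seed through named substreams, so a change
to one generator's parameters never shifts another's draws, and a spec
regenerates its bundle byte-for-byte.

What passing tests on this world **does not** show: agreement with any real
country's values (the generator makes no attempt to match real activity
data), robustness to the messiness of real field datasets (inconsistent
units, partial controls, covariate-dependent EFs), or the validity of the
restricted manufacturing/transport EF values themselves — the package only
defines their slots and uncertainty treatment, and accepts user tables.

## Problem sizes and scale

The default world (45 countries, ~780 plots, 5,000 MC draws over ~200 EF
specs) runs the full pipeline in a few seconds; the test suite and the
acceptance script use this scale throughout, with parameter-recovery checks
at 200 plots per country over 20 seeds. Published world-row figures enter
only as inputs to consistency checks (shares, CVs, intensity, unit
conversions); the headline absolute totals of the real 2018 inventory are
not reproducible here because they require the licence-restricted EF tables
and the FAO activity snapshot.

## Known limitations

* EF covariates (crop, rate, soil, management) are out of scope; estimation
  uses simple weighted means, as in the inventory methods this implements.
* No uncertainty on activity data, and no spatially-explicit allocation
  within countries (a country is wholly wet or dry).
* Manufacturing uses the consuming country's region as region of production
  unless an explicit mapping is supplied; trade detail enters only through
  the sourcing mix.
* The life-cycle boundary is factory gate → field: no farm machinery,
  irrigation energy, or land-use change.
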