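---
title: "Methods: counterfactual deforestation-leakage analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual deforestation-leakage analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the approach

Zero-deforestation supply-chain policies (ZDSPs) bar committed commodity
traders from buying soy grown on recently cleared land. They bind only where
committed traders dominate the local market, so forest conversion can be
displaced — "leak" — to municipalities, biomes or countries outside the
policy's footprint. Because the policies of interest (importer regulations in
the EU or China, global voluntary pledges) have mostly never been
implemented, leakage cannot be measured ex post; it has to be simulated as
the difference between a counterfactual world with the policy and a baseline
without it.

`soyshift` implements that full counterfactual pipeline at desk scale:

1. a **synthetic mini-world generator** (balanced social accounting matrix,
   municipality land-cover layer, trader-level export table) standing in for
   the global trade database, the municipality land-cover maps and the
   trader-flow data the full-scale study consumed;
2. a **footprint stage** that classifies municipalities by
   committed-trader market share and splits the policy country's accounts
   into biome x AEZ x compliance land cells;
3. a **multi-region applied general-equilibrium (AGE) model** with a nested
   land-supply structure, solved in levels by damped Newton;
4. an **endogenous-subsidy conversion freeze** implementing the policy;
5. **leakage-rate decomposition** and **land-use-change GHG accounting**;
6. an orchestration layer for the 30-run scenario grid and a Monte-Carlo
   sensitivity sweep.

Everything runs from a single seed with no downloads. The published headline
magnitudes (hundreds of kha of avoided deforestation) come from the
full-scale global databases and are *not* reproducible from a synthetic
mini-world; they enter the package only through
`verify_printed_arithmetic()`, which recomputes every derived headline
number (leakage rates, annualizations, cross-scenario ratios, emission
shares) from the raw printed inputs bundled in
`inst/extdata/published_headline_values.csv`. All simulation-based claims are
property-based: signs, orderings, conservation laws and convergence, checked
by the test suite and the acceptance script.

# The equilibrium model

## Structure

Each region has one representative activity per sector. Technology is
Leontief in intermediate composites over a CES value-added nest of labor,
capital and — for land-using sectors — a CES composite of cover-specific
land across the region's cells. Trade follows the Armington structure:
buyers combine the domestic variety with an import composite (elasticity
`armington1`), and the import composite combines origins (`armington2`).
One representative household per region owns all factors and spends through
a linear expenditure system (LES) calibrated from income elasticities and a
Frisch parameter. There is no government and no international borrowing, so
regional trade balances endogenously through the budget constraint.

Benchmark prices are normalised to one (the standard AGE calibration
convention), so every CES/CET share coefficient equals a benchmark value
share read off the balanced SAM, and the solver works in ratios to the
benchmark. The numeraire is the primary-factor price index of the first
region; `solve_equilibrium()` verifies Walras' law and homogeneity rather
than assuming them.

## Land supply

Land within each cell moves through a three-level nest that separates the
decision to convert natural cover to agriculture from the decision to
convert pasture to cropland (deforested land transitions first into pasture,
then into cropland):

* level 1 — forest, natural grassland, other natural cover, agricultural
  land (`sigma_nat`, the deforestation margin);
* level 2 — pasture vs cropland (`sigma_agpast`);
* level 3 — cropland across crops (`sigma_crop`).

Forest earns the forestry sector's market rent; the non-forest natural
covers earn a reservation rent that is a real constant (it scales with the
numeraire — a fixed *nominal* reservation rent would anchor the price level
twice and break homogeneity, which the test suite checks).

Two standard CET variants are implemented in `cet_allocate()`. The
`"frontier"` variant is textbook revenue maximization on a transformation
frontier calibrated through the benchmark; it is validated against a
brute-force grid-search oracle (`cet_frontier_oracle()`). Like every
frontier CET it conserves the transformation aggregate, not physical
hectares. The `"additive"` variant is the sum-preserving relative-rent-share
form (the aggregate allocation of a continuum of plots with idiosyncratic
returns); child areas add to the parent exactly at every nest level. The
equilibrium model uses the additive variant so that physical land is
conserved exactly on every run — a design choice we consider the right
trade-off at desk scale, where exact conservation laws are what the tests
lean on; the frontier variant remains available and oracle-checked.

## Policy implementation: the conversion freeze

`apply_zdsp()` halts conversion in compliant cells by a constraint swap: the
restricted cover (forest under definition A; forest plus natural grassland
outside the Amazon under definition B) is held at its benchmark area
(exogenous), and the compensating retention subsidy becomes endogenous — the
rent wedge that rationalises the frozen share in the unconstrained
allocation rule, solved in closed form per cell. This is mathematically
equivalent to iterating on a subsidy until the area target is met, but
numerically cleaner. Subsidy receipts and payments net out inside the
regional household, so the instrument affects only the allocation margin and
leaves Walras' law intact. Under expansionary drivers the subsidy is
nonnegative; the tests assert both the exact freeze and the subsidy sign.

## Solver

The market-clearing system (zero profit, goods, factor and land markets,
numeraire) is solved in levels by damped Newton with a finite-difference
Jacobian, step halving, and chord-Newton reuse of the factorised Jacobian
between iterations (rebuilt when progress stalls and always in the endgame).
Tolerance is 1e-9 on the maximum scaled residual; benchmark replication and
Walras residuals are reported on every solve. Non-convergence raises an
error with the residual trace — never a silent bad state. On the default
5-region x 6-sector world with compliance-split cells the system has about
130 unknowns and solves in roughly a second.

# The synthetic world

## What it emulates

The generator draws, under one explicit seed: a municipality table (biome,
AEZ, land covers, soy area and production, second-harvest maize on soy area,
cattle), a trader roster with commitment flags and destination propensities,
a municipality x company x destination export-volume table, and a balanced
SAM whose land accounts sit at biome-AEZ resolution for the policy country.
Raw value flows are laid out from structural priors (sector output shares by
region role, input-output cost structure, trade affinities) and balanced by
RAS (`balance_matrix()`, relative tolerance 1e-12); land rents per cell are
imputed proportional to area times a biome productivity factor, since the
rent database the full-scale study used cannot be shipped.

Structural features of the real soy market are encoded deliberately,
because the leakage mechanisms run through them:

* **Destination segmentation** (`destination_segmentation` in [0, 1]): the
  policy country's soy exports concentrate on China while the neighbouring
  frontier (the Bolivia-Argentina-Paraguay analogue, "BAP") serves the EU;
  at 1, every exporter ships to exactly one destination. China and the US
  compete in the same import market, which tightly connects their supply
  responses.
* **An import-dependent main market**: the China-dominated aggregate
  imports most of its soy, and it is not an active forest-conversion
  frontier (`sigma_nat` 0.03), so marginal supply comes from the policy
  country and the spare-land competitor.
* **A spare-land competitor** (the US-Canada analogue) with a negligible
  forest-conversion margin (`sigma_nat` 0.02): displaced soy is absorbed
  into existing farmland rather than new clearing.
* **Essentially non-traded grazing livestock** (export share 2%, Armington
  1.5): forest conversion abroad responds to crop markets, not to a
  fictitious world market for live cattle.
* **Income-inelastic timber demand** (income elasticity 0.1, Cobb-Douglas
  forestry value added): over a five-year horizon forest rents lag
  agricultural rents, so expansionary drivers clear forest — the observed
  baseline condition.

Foreign land endowments are stated as multiples of the generated policy
country's total area (frontier 0.8x, spare-land 1.6x, EU 1.1x, rest 6x), so
hectare deltas are commensurate across regions rather than artifacts of
arbitrary absolute sizes.

## What it does not emulate

No rasters, no geometry: the municipality-to-AEZ/biome assignment that a GIS
overlay would produce is generated directly (and `assign_cell()` implements
the largest-intersection / biome-stringency rules for callers who do have
overlay fractions). The mini-world has tens of municipalities, not five
thousand; one aggregate land cell per foreign region; and no multi-year
dynamics. Passing tests therefore demonstrate that the *pipeline and
mechanisms* behave correctly — conservation, monotonicity, sign structure,
the segmentation ordering — not that the synthetic magnitudes match any
observed country.

## Drivers

The medium-run drivers (`default_drivers()`) represent the five-year window
between the benchmark and the horizon year as proportional changes chosen
once at plausible magnitudes: labor endowment growth of 2-8% and capital
growth of 6-30% by region (fastest in the China aggregate), Hicks-neutral
agricultural productivity growth of 4%, biofuel-driven oilseed-demand shifts
of +25% in the US and EU, and +40% feed/protein import demand in the China
aggregate. The period length for annualization is 5 years, which is also the
divisor that reproduces the printed annualized avoided-deforestation figures
exactly. The moratorium is excluded from the baseline so that its own effect
can be reported against it.

# Scenarios, thresholds, definitions

Five scenarios (moratorium-only; plus global voluntary pledges; all
companies exporting to the EU; to China; to either), three market-share
thresholds (> 0%, >= 50%, >= 75%, inclusive bounds as printed and
unit-tested at the boundary), and two forest definitions (A: forest only;
B: plus natural grassland outside the Amazon) give the 30-run grid. A
company selling any volume to a regulated destination commits its entire
supply chain (supply-chain differentiation is assumed prohibitively costly),
and the moratorium footprint is OR-ed into every wider scenario.
Municipalities with no exports have no buyer leverage and are non-compliant
under every threshold; their count is logged on the compliance map.
Because the compliance split and the baseline depend only on scenario and
threshold, they are shared between the two forest definitions inside
`run_grid()`.

One modelling consequence of the desk-scale design: the two forest
definitions share one land database and differ only in which covers the
counterfactual freezes, whereas the full-scale study rebuilt its land
database per definition. At biome-AEZ resolution with generated covers the
two constructions coincide.

# Leakage and emissions accounting

`diff_land()` differences two equilibria cell by cell (counterfactual minus
baseline; positive forest deltas are avoided deforestation) and partitions
forest deltas into the frozen footprint, uncovered domestic cells, and
foreign cells; global = footprint + rest holds exactly by construction and
is asserted to machine precision. `build_report()` converts to kha and
computes the domestic and cross-border leakage rates as displaced clearing
over gross avoided clearing, in percent; rounding happens only at the
presentation layer.

`emissions_from_deltas()` maps each cell's net cover deltas to gross
transitions (losses to gains, proportionally — a comparative-static model
yields net areas, not gross flows, the same simplification class the
established emission-factor tooling makes for such inputs) and applies a
per-cell factor matrix built from per-cover carbon stocks (biomass, dead
organic matter, soil) plus foregone sequestration, a wood-product storage
credit and a non-CO2 term, over a 30-year horizon. Reverse (regrowth)
transitions are credited at a 50% discount by default rather than treated
as symmetric. Carbon stocks are configurable inputs with biome-typical
synthetic defaults (`default_carbon_stocks()`), not constants of the
method; foregone sequestration is included in the per-hectare factor by
default and exposed as an assumption.

# Sensitivity analysis

`sensitivity_sweep()` re-solves one scenario under independent uniform
multiplicative draws (default x[0.5, 2]) on the transformation elasticities
of the three land nests and the Armington elasticities — Monte Carlo rather
than the Gaussian-quadrature systematic sensitivity analysis common in this
model family, for simplicity and seed-based reproducibility at desk scale.
It reports the 5-95% interval of the leakage rates and the fraction of
draws in which net global avoided deforestation stays positive (the
sign-stability statistic). The default is 50 draws.

# Numerical choices and degenerate inputs

* RAS balancing: relative tolerance 1e-12; structural zeros preserved; an
  infeasible zero pattern names the offending row or column. Household
  targets are reconciled with the single-entry factor columns before
  iterating, which the RAS support structure requires.
* Solver: tolerance 1e-9, at most 40 iterations, positivity-preserving step
  cap, chord-Newton with stall-triggered refresh.
* Invariant tests run at 1e-6 unless the quantity is exact by construction
  (the freeze, the additivity decomposition), where they assert equality.
* Zero-export municipalities yield an undefined market share, logged and
  non-compliant. Zero-volume land nests are skipped; a factor no household
  owns has its price pinned to the benchmark instead of an empty market
  equation. Cells frozen under definition B inside the Amazon reduce to
  definition A, as the definitions coincide there.
* All randomness flows through explicit seed arguments; global RNG state is
  saved and restored around every generator.

# Problem sizes

The shipped configuration is 5 regions x 6 sectors, 60 municipalities, 12
companies, 2 AEZs per biome — about 130 unknowns per solve after the
compliance split, roughly a second per solve, a minute for the 30-run grid
and about two minutes for the 50-draw sweep. The full 11-region and
18-sector aggregations of the original study are available as presets
(`regions_preset_11()`, `sectors_preset_18()`); the machinery is generic in
both dimensions.

# Known limitations

* Magnitudes are synthetic; only arithmetic identities on the bundled
  printed values connect the package's numbers to the published ones.
* One land cell per foreign region hides within-region heterogeneity of
  cross-border leakage.
* The medium run is a single comparative-static step; no recursive dynamics,
  no capital mobility across regions (capital is mobile across sectors
  within a region, a deliberate medium-run closure).
* The LES is a coarse demand system at large income changes; income
  elasticities are held at calibration values.
* The calibrated transformation and trade elasticities of the original
  study live in external sources; the defaults here are documented
  placeholder values whose influence is bounded by the sensitivity sweep,
  and no acceptance property depends on their point values.
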