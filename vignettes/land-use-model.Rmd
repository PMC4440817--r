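---
title: "An agent-based model of rural land-use change under GHG pricing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of rural land-use change under GHG pricing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farmscape)
```

## The model

`farmscape` simulates enterprise conversion on a catchment of cadastral
farm parcels. The design separates three layers:

1. **Landscape** — parcels on a 25-ha raster with an area, centroid,
   productivity zone (Plains, Foothills, Hills, mapped from Land Use
   Capability classes 1–4, 5–6 and 7–8) and a single current
   enterprise. Farms of 100 ha or less, farms whose predominant use is
   outside Dairy / Sheep & Beef / Plantation Forestry, and Crown land
   carry no farmer agent.
2. **Farmer agents** — one per farm, heterogeneous in life-cycle stage,
   successor status, and realised profitability. All heterogeneity except
   succession acts through a single quantity: the *likelihood of land-use
   conversion*.
3. **Economics** — a per-farm net-revenue maximiser over an
   enterprise-by-zone budget table. This is deliberately simple: it
   plays the role a coupled partial-equilibrium farm model would play,
   and what the agents consume from that coupling is exactly a
   revenue-maximising proposal plus expected net revenues. The maximiser
   reproduces that interface from a configurable coefficient table.

A step represents five years; the default horizon is ten steps. Each
step runs in fixed phases: market update → forest-lock decrement →
agent decisions in a seeded random order → demography (life-cycle
advance, farm sales) → ledger recording. Agents read neighbour states
as of the start of the step (synchronous read, asynchronous write), so
the evaluation order only affects which random draws each agent
consumes — without this, a fixed ordering would bias imitation toward
farms evaluated early.

### The decision rule

If the proposed (revenue-maximising) enterprise equals the current one,
the farmer only updates their net revenue; no randomness is consumed.
Otherwise the conversion likelihood starts at its base value (0.2,
reset after every decision), is adjusted by the two network mechanisms,
then constrained:

* **Endorsement** (±0.1): own profitability/ha versus the equally
  weighted mean of the ten closest farmers in the same enterprise.
* **Imitation** (±0.05): own profitability/ha versus geographically
  adjacent farms already running the proposed enterprise. The magnitude
  is deliberately half the endorsement effect.
* A farm inside its forest rotation lock has likelihood 0 — adopting
  either forest enterprise commits the farm for the minimum economic
  stand age of 25 years (5 steps).
* A proposal to convert *into* Dairy is cut by 75 %, a reduced-form
  stand-in for conversion capital and lifestyle costs that are not
  modelled as cash flows.

A uniform draw below the final likelihood converts the farm. With
networks disabled the final likelihood can only be 0, 0.05 (Dairy
proposal) or 0.2 — a property the test suite checks exhaustively.

### Succession

Farmers move through a five-stage generational cycle, one stage per
step by default. Stage 1 triggers a successor assessment (success
probability 0.75); completing Stage 5 with a successor resets the agent
to Stage 1 (takeover); without one, the farm is sold. The sale replaces
the operator (farm and farmer counts are conserved) and gives the new
owner one immediate conversion evaluation at the base likelihood with
constraints applied but network adjustments omitted: a minimal
mechanism for the "new owner's preferences" opportunity that does not
invent preference heterogeneity. Two points the five-stage framing
leaves open were resolved as follows: agents initialised mid-cycle
(initial stages are uniform on 1–5, which avoids synchronised sale
waves) receive a successor draw at creation, as does the replacement
farmer after a sale — otherwise mid-cycle initialisation would make
early sales deterministic artefacts of initialisation rather than
outcomes of the succession probability.

## Economics and GHG accounting

The per-hectare annual margin of enterprise *e* on zone *z* at step *t*
is `r`·(1+g)^(5t) − c − τ·E + τ·S·[e = CarbonForestry]. Commodity
revenue grows at g = 2 %/yr; costs are held in real terms (the growth
assumption concerns output prices; technology is constant). The GHG
price τ is charged directly on per-ha livestock emissions — in the
system being modelled the charge arrives indirectly through processors,
but the farm-level incidence is the same. Plantation forestry is
outside the charge in both directions; Carbon Forestry (permanent,
unharvested plantings) is paid τ per tonne sequestered.

Environmental accounting is by export coefficients: gross GHG is the
area-weighted sum of livestock emissions; **net GHG = gross − forest
sequestration**, where both forest enterprises sequester physically even
though only Carbon Forestry is paid. N leaching and P loss are per-ha
export sums.

### The default coefficient table

No real-catchment farm-economics calibration is distributed with the
package, so the shipped defaults (`default_coefficients()`) are a
*qualitative* calibration chosen once to reproduce the orderings the
model's behaviour turns on, with magnitudes that are placeholders:

* Dairy is the most profitable enterprise on Plains and Foothills at
  τ = 0, and infeasible on Hills.
* Forestry beats Sheep & Beef on Hills at all prices.
* Carbon Forestry overtakes plantation Forestry on Hills only as τ
  reaches $60/tCO2e, and only early in the horizon (its carbon payment
  is fixed while timber revenue grows with the commodity index).
* Rising τ flips the Foothills argmax from Dairy to Forestry for a
  widening window of early steps (τ = 20: step 1; τ = 40: steps 1–2;
  τ = 60: steps 1–3), so forest expansion and the net-GHG decline
  respond gradually to the price, strongest immediately after the
  policy shock.

Users studying a real catchment should supply their own table
(`read_coefficients()`), at which point these orderings are theirs to
calibrate.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `initial_likelihood` | 0.2 | probability | base conversion likelihood, reset after every decision |
| endorsement delta | ±0.1 | probability | social network of `k_social` = 10 closest same-enterprise farmers |
| imitation delta | ±0.05 | probability | adjacent farms running the proposal; half the endorsement weight |
| `dairy_penalty` | 0.75 | fraction | multiplicative reduction of Dairy proposals |
| `forest_lock_steps` | 5 | steps | 25-year minimum rotation |
| `succession_rate` | 0.75 | probability | Stage-1 successor assessment |
| `annual_price_growth` | 0.02 | /yr | real commodity price growth |
| `years_per_step` | 5 | yr | step length |
| `n_steps` | 10 | steps | 50-year horizon |
| `ghg_price` | 0–60 | NZD/tCO2e | constant per scenario (a schedule hook exists but the experiment design imposes one price per scenario) |
| `min_area_ha` | 100 | ha | strict farm filter ("in excess of") |

The experiment defaults are prices $0–$60 in $10 increments, both
network arms, and 50 seeds — 700 runs in total; the grid is fully
configurable.

## The synthetic landscape generator

`generate_synthetic_landscape()` emulates the *structure* of a
New Zealand hill-country pastoral catchment, not any real geography: a
rectangular grid of 25-ha cells in
three zone bands (35 % Plains, 35 % Foothills, 30 % Hills of rows),
partitioned into contiguous parcels by seeded region growing with
log-normal target sizes (median 7 cells ≈ 175 ha, truncated at 4 cells
= 100 ha; undersized remnants are merged into neighbours). Initial
enterprises are drawn per parcel from zone-level target shares
dominated by Sheep & Beef, with minor Dairy concentrated on the Plains
and Forestry on the Hills. Geographic adjacency is rook (edge-sharing)
contiguity on the cell grid — corner-only contact is excluded to avoid
degenerate one-point neighbours — and "closest" in the social network
is Euclidean distance between parcel centroids on planar coordinates
(no geodesy; distances are only ranked).

The default catchment is 40 × 30 cells (30,000 ha, ~120–150 farms), a
deliberately desk-scale instance: large enough for distinct zone bands,
meaningful nearest-neighbour structure and stable ensemble means, small
enough that a 700-run experiment is routine. What the generator does
**not** emulate: real cadastral shapes and size mixes, spatial
autocorrelation of land quality within zones, roads/rivers, irrigation,
and any heterogeneity of coefficients *within* an (enterprise, zone)
pair. That last simplification matters for interpretation: profitability
per hectare is identical for all farms of one enterprise in one zone, so
endorsement differences arise only across zone boundaries and tests
passing on this landscape show mechanism correctness, not empirical
adequacy for a real catchment.

## Numerical and reproducibility choices

* **Tie-breaks.** Optimiser ties: the current enterprise wins if among
  the maxima, otherwise the first maximiser in the fixed order Dairy,
  SheepBeef, Forestry, CarbonForestry. Majority-area ties in
  predominant-use resolution: the same fixed order (lowest wins).
  Distance ties in the social network: lowest parcel id. Exactly equal
  profitability comparisons yield a zero delta.
* **Profitability timing.** Network comparisons read the *previous*
  step's realised profitability, avoiding within-step order dependence.
* **RNG.** Each run derives four named substreams (landscape, initial
  stages, decisions, demography) from the run seed, so toggling one
  mechanism never shifts another's draws. The landscape substream is
  keyed to `config$landscape$seed` (fixed by default) so all runs of a
  scenario share one landscape — parcel-level probabilities across runs
  require it. Identical (config, seed) pairs reproduce ledgers exactly.
* **Clamping.** The likelihood is clamped to [0, 1] after summing
  deltas; with default parameters the maximum is 0.35, so clamping only
  binds under user-modified settings.
* **Degenerate inputs.** Empty networks give zero deltas; an empty
  post-filter landscape, infeasible initial enterprises, malformed
  share vectors and out-of-range LUC classes are hard errors naming the
  offending parcels.
* **Pre-existing forests** start unlocked at t = 0 (initial stands are
  treated as mature); only conversions *into* forest start the 5-step
  lock.
* **Confidence intervals** are the normal approximation
  mean ± 1.96·sd/√n over seeds.

## What the tests establish

The test suite covers the contracts above: conservation of catchment
area, the decision identity (converted ⇔ draw < likelihood), the
exact 5-step forest lock, net GHG = gross − sequestration to machine
precision, seed reproducibility, and oracle equivalence of the
optimiser (brute-force argmax over random tables) and the social
network (all-pairs distance sort). Problem sizes were chosen so the
full suite exercises every mechanism at ensemble scale: unit tests run
on a 20 × 15-cell catchment (~40 farms), the generator share check on a
~2,000-parcel catchment over 20 seeds, and the qualitative scenario
signatures on the default 40 × 30 catchment with 50 seeds per scenario
arm at τ ∈ {0, 20, 40, 60}. Those signatures — mean final-step net GHG
non-increasing in τ, forest area weakly increasing, Foothills Dairy
share raised by network effects at every price — are *sign* tests under
the default synthetic calibration; no magnitude from a real catchment
is asserted anywhere, because none is recoverable from public inputs.

## Known limitations

Single enterprise per farm (no within-farm mix or management options);
no conversion capital cash flows beyond the Dairy penalty; no input or
output price endogeneity at catchment level; no irrigation expansion,
climate or technology change; equal stature within social networks; no
farm amalgamation at sale (the buyer is always a new agent); planar
coordinates without CRS handling; ESRI shapefile input is not supported
(use GeoJSON or the tabular formats).
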