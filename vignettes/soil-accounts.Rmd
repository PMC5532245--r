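---
title: "Biophysical soil accounts: methods and design choices"
author: "soilcapital"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biophysical soil accounts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilcapital)
```

## The accounting model

National accounting frameworks in the SEEA (System of
Environmental-Economic Accounting) family record the state of an
environmental asset as a stock at the opening and closing of a period,
with all change decomposed into additions and reductions. `soilcapital`
applies this structure to the soil resource, reported by land cover
rather than by soil type: policy acts on land use, so changes in the
soil asset are most legible when booked against the cover class under
which they occur. Three account families are implemented.

**Extent accounts.** Land territory is classified into the 14 interim
SEEA land-cover classes (codes 1–14; `seea_classes()`). Grids in the
44-code CORINE nomenclature are first aggregated by a total mapping
(`aggregate_classes()`; the default packaged mapping assigns, e.g., all
three forest codes and transitional woodland-scrub to *Tree covered
areas*). For an epoch pair the change matrix
$F_{ij}$ — the area that moved from class $i$ to class $j$ — is a
cross-tabulation of the two co-registered grids (`change_matrix()`).
The account for class $j$ is then

$$\mathrm{closing}_j = \mathrm{opening}_j + A_j + R_j,$$

with additions $A_j \ge 0$ and reductions $R_j \le 0$. In *net* mode
(the published layout) $A_j + R_j = \sum_i F_{ij} - \sum_i F_{ji}$ and
only one of the two is nonzero per class; *gross* mode books total
inflow and outflow separately, because net aggregation can hide large
compensating flows (a class can simultaneously gain and lose substantial
area). Flows on classes under direct economic management — artificial
surfaces and the three cropped systems by default — are booked as
*managed* expansion/regression, all others as *natural*. Reappraisal
rows exist in the layout but are always zero here.

**Mass accounts.** For each accounted cover class (the eight
terrestrial vegetated or bare classes; artificial, mangrove, aquatic,
snow and water classes carry no soil mass flows) the balance is

$$\mathrm{closing} = \underbrace{a \cdot r_f}_{\text{formation}}
 + \underbrace{D}_{\text{deposition}}
 - \underbrace{D}_{\text{redeposited}}
 - \underbrace{L}_{\text{lost to watercourses}},$$

where $a$ is the class area (ha), $r_f$ a soil-formation rate bound,
and gross rill-and-sheet erosion mass $G = a \cdot r_e$ is partitioned
by a sediment-delivery fraction $d$ into loss $L = d\,G$ and on-land
redeposition $D = G - L$ (`partition_erosion()`). Because deposition and
redeposition cancel — within-territory redistribution is mass-neutral —
the closing stock change is algebraically $a r_f - L$; the full ledger
is still emitted because the component flows are informative (dredging,
reservoir siltation, off-site damages scale with $L$, not with the
net).

**Condition cross-tabs.** Topsoil point samples (LUCAS-style: SOC in
g/kg, pH, a map-derived peat flag) are classified into four
organic-carbon groups and six pH bins, and sample proportions are
converted to hectares by cover: with $n_c$ samples on cover $c$ of
which $n_{ck}$ fall in condition class $k$,

$$\widehat{\mathrm{area}}(c, k) = \mathrm{area}(c) \cdot n_{ck} / n_c.$$

This design-based proportional estimator treats each cover's samples as
an equal-probability sample of its area; rows sum to the cover areas
exactly.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| formation rate bounds | 0.4 – 1.4 | t ha⁻¹ | Bracket of published soil-production estimates for European conditions; cosmogenic-nuclide work on granite-derived soils (~0.15 mm yr⁻¹ ≈ 1.6 t ha⁻¹) supports the upper bound's magnitude. |
| `delivery_fraction` | 0.10 | – | Fraction of gross eroded mass reaching watercourses. Not a universal constant — catchment studies put the sediment delivery ratio anywhere from ~98% (field scale) to ~2% (large basins). The default is the whole-territory value embedded in the packaged EU-25 account (every class's printed loss/gross ratio is 0.100); override per application. |
| peat threshold | 0.35 | probability | A cell is peat when the mapped peat probability strictly exceeds 35%; peat classification overrides measured SOC because the source peat map, not concentration, defines the class. |
| SOC thresholds | 120, 30 | g/kg | Organo-mineral above 12% SOC (strict), humus-mineral 3–12% (closed), mineral below 3% (strict). Interface unit is g/kg, the survey convention. |
| pH breakpoints | 4.5, 5, 6, 7, 8.3 | pH | Bins lower-inclusive except the closed top of 7–8.3 (so exactly 8.3 is not ">8.3"). End breakpoints are physically meaningful (Al toxicity < 4.5; B toxicity / sodicity > 8.3); interior ones are display conventions. |
| `min_mapping_unit` | 0 | km² | CORINE change layers suppress changed patches under 5 ha (0.05 km²); synthetic grids are unfiltered, so filtering is opt-in. |
| `years` | 1 | – | Period multiplier on all rates; see below. |

### Boundary conventions

The source material calls its condition divisions "mostly arbitrary",
so the tie-breaking at the breakpoints is a package convention, stated
once and tested: 120 g/kg and 30 g/kg are both humus-mineral (the outer
thresholds are strict); pH 4.5 belongs to "4.5–5" and pH 7 to "7–8.3"
(lower-inclusive), while 8.3 itself stays in "7–8.3" (the top bin is
strictly greater).

### The `years` ambiguity

The published EU-25 mass account is headed by a 12-year period, yet its
formation cells equal rate × area × 1, not × 12. The package reproduces
the table with `years = 1` (i.e. the account is per rate-unit period)
and exposes the multiplier rather than resolving an ambiguity the
source leaves open. Likewise, the per-class areas implied by the mass
account do not match the extent account's areas (e.g. ~1.10 Mkm²
implied versus 0.94 Mkm² for herbaceous crops); areas are therefore an
explicit input, with the mass-account-implied values shipped as the
packaged fixture.

## Packaged EU-25 inputs

Two small input tables ship with the package. The extent inputs
(`eu_extent_inputs()`) are the published opening areas and net flows
verbatim; because the printed net flows sum to +1 km² rather than 0
(source rounding), the account is assembled per class from the identity
via `extent_account_from_net()` rather than through a change matrix,
and validation uses the internally consistent classes. The mass inputs
(`eu_mass_inputs()`) are *back-solved*: each class area is the value
that reproduces both printed formation cells under
half-away-from-zero rounding, and the gross rate is printed gross mass
divided by that area (≈2.67, 9.47, 4.21, 2.57, 0.23, 3.87, 40.76,
20.90 t ha⁻¹ for classes 2, 3, 4, 5, 6, 8, 10, 11). With these inputs
the engine reproduces all printed closing stocks within ±1 t.

## Numerical choices

* Areas are carried in km² (ha in the mass account) at full precision;
  rounding to integers happens only at report-writing time, using
  round-half-away-from-zero because that is how the published tables
  round.
* In `partition_erosion()` the loss is rounded first and redeposition
  takes the remainder, so the written pair always sums exactly to gross
  erosion.
* Unknown account cells (opening soil stock, sealed mass, mangrove
  extent, classes without mass flows) are `NA` internally and empty in
  CSV output — never 0, which would assert knowledge the account does
  not have.
* Minimum-mapping-unit filtering labels 4-connected patches of cells
  undergoing the *same* class-to-class transition and folds patches
  strictly below the threshold back onto the matrix diagonal.
  4-connectivity was chosen because diagonal-only adjacency does not
  constitute a contiguous mapped patch at the source data's resolution.
* Grids must share shape, cell size and nodata mask; a cell classified
  in one epoch and nodata in the other is an error, not a flow. No
  reprojection or resampling is performed.
* Nearest-sample ties in the change cross-tab break to the lowest
  `sample_id`, making the assignment deterministic.

## What the synthetic generator emulates — and what it does not

`scenario()` bundles a grid shape, an initial class mixture with a
patchiness scale, a per-epoch Markov transition matrix, and per-cover
soil distributions. Initial grids are grown from random nuclei (one per
`patchiness²` cells) by multi-source breadth-first search, giving
contiguous patches with unbiased expected class shares; epochs advance
by independent per-cell draws from the transition matrix; SOC is
lognormal (non-negative, right-skewed), pH truncated-normal on (3, 10),
peat Bernoulli, all per cover. The default parameters
(`default_cover_params()`) encode the qualitative pattern of European
survey data — tree-covered and wet soils carry the highest SOC, crops
sit near-neutral in pH, woodland is acidic, peat concentrates under
aquatic/flooded vegetation. The packaged `eu25_toy_scenario()` mirrors
the EU-25 situation at toy scale: class shares follow the published
opening shares, and per-epoch transition probabilities of a few per
mille reproduce the observed magnitude of change (under 1% of territory
per class per period), with crops losing ground to artificial surfaces
and woodland gaining.

The generator deliberately omits features of real data: there is no
spatial correlation in soil properties given cover (draws are
independent), no spatially heterogeneous transition probabilities (real
urbanization clusters at city fringes), no class-dependent patch-size
distributions, and no emulation of erosion-model surfaces or of real
survey marginals. Consequently, passing recovery tests demonstrates
that the *pipeline* is unbiased under known generating conditions — it
does not validate the substantive European numbers, which depend on the
external land-cover, erosion and survey inputs.

## Validation strategy and problem sizes

Every estimator is checked two ways: against tiny hand-computed or
brute-force oracles (naive per-cell change tallies, exhaustive
nearest-neighbour search, hand ledgers), and by parameter recovery on
simulated data, with all deviations bounded at three standard errors of
the generating process. The shipped test suite uses grids up to
200 × 200 cells, 500 brute-force trials on grids up to 50 × 50, and
5,000-sample condition recoveries — sizes at which every binomial bound
is tight enough to be informative while the whole suite runs in
seconds. `scripts/acceptance.R` re-runs the same computations from
scratch and reports the resulting quantities as JSON.

## Known limitations

* The proportional area estimator ignores unequal inclusion
  probabilities and any post-stratification a real survey design would
  carry; the change cross-tab's nearest-sample attribution is a
  simplification with no variance estimate.
* Carbon stocks (t C) are out of scope: they require bulk density,
  which the emulated survey round does not carry.
* The sediment-delivery fraction is a single territory-wide scalar; no
  catchment routing or delivery-versus-area relation is modelled.
* Erosion rates are inputs by land-cover class; the package does not
  compute erosion (no RUSLE factors) and covers only rill-and-sheet
  erosion — published rates of that kind are likely a lower bound on
  total erosion.
* GeoTIFF input reads the pixel band only; there is no georeferencing,
  reprojection or vector support.
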