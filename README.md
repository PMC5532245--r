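# soilcapital

Biophysical natural-capital accounts for soil, in the style of the UN
System of Environmental-Economic Accounting (SEEA), reported by land
cover. The package is for environmental accountants, soil scientists and
policy analysts who need to turn gridded land-cover products, per-class
erosion rates and topsoil survey points into the three account families
that describe the state and change of the soil resource:

* **Extent accounts** — CORINE-coded land-cover grids are aggregated to
  the 14 interim SEEA classes, epoch-to-epoch change matrices
  `F[i, j]` (area moving from class *i* to class *j*) are
  cross-tabulated with optional minimum-mapping-unit filtering, and the
  account identity `closing = opening + additions + reductions` is
  assembled per class, with flows split into managed and natural
  expansion/regression.
* **Mass accounts** — a per-class soil mass balance
  `closing = a·r_f − L`, where `a·r_f` is soil formation under a low
  (0.4 t/ha) or high (1.4 t/ha) rate bound and gross rill-and-sheet
  erosion `G = a·r_e` is partitioned by a sediment-delivery fraction
  `d` (default 0.10) into loss to watercourses `L = d·G` and on-land
  redeposition `D = G − L` (mass-neutral for the territory, but booked
  on both sides of the ledger).
* **Condition cross-tabs** — LUCAS-style topsoil samples are classified
  by organic carbon (peat; organo-mineral > 12% SOC; humus-mineral
  3–12%; mineral < 3%; peat is map-defined and takes precedence) and by
  six pH bins (breakpoints 4.5, 5, 6, 7, 8.3), and sample proportions
  are converted to hectares per cover by the design-based estimator
  `area(c, k) = area(c)·n_ck/n_c`.

A synthetic-data module generates patchy categorical land-cover grids
evolving under a known Markov transition matrix, per-cover soil-sample
distributions and peat-probability surfaces, so the whole pipeline is
testable by parameter recovery without any external data. YAML-driven
pipeline functions (`run_simulate()`, `run_extent()`, `run_mass()`,
`run_condition()`) and a thin command-line wrapper
(`inst/cli/soilcap.R`) tie the stages together with seeded,
manifest-checksummed outputs.

## Worked example: the EU-25 accounts

The packaged inputs reproduce the published EU-25 accounts for the
2000–2012 period. The extent account from the published opening areas
and net flows:

```r
library(soilcapital)
eu_extent_account()
#> Land-cover extent account (net mode), 2000 -> 2012
#>  code                         name opening total_additions total_reductions closing
#>     1          Artificial surfaces   99128            8354                0  107482
#>     2             Herbaceous crops  941477               0            -8676  932801
#>     3                  Woody crops   88041            1596                0   89637
#>     ...
#>     6           Tree covered areas 1270472            4049                0 1274521
#>     7                     Mangrove      NA               0                0      NA
#>    13          Inland water bodies  155996             815                0  156811
```

Artificial surfaces expanded by 8,354 km² (managed expansion, closing
107,482 km²) while herbaceous crops regressed by 8,676 km² — urban
sprawl taking arable land — and tree cover grew by 4,049 km². Mangrove
is absent from Europe and is carried as missing, never zero.

The mass account from the packaged per-class areas and gross erosion
rates:

```r
ma <- eu_mass_account()
subset(net_balance_summary(ma), !is.na(net_high))
#>    code                             name   net_high depleting
#> 2     2                 Herbaceous crops -140290455     FALSE
#> 6     6               Tree covered areas  185392181     FALSE
#> 10   10 Sparsely natural vegetated areas -149012521      TRUE
#> 11   11          Terrestrial barren land   -2289613      TRUE
```

`net_high` is formation at the optimistic 1.4 t/ha bound minus gross
erosion (tonnes). Sparsely vegetated and barren land are *depleting*:
their closing stock change is negative (−10,130,812 t and −81,032 t)
even under the high formation bound. Tree-covered areas are the clear
counter-example — formation outpaces erosion several-fold. For
herbaceous crops the sign of the balance depends on which formation
bound is believed (closing +125,156,728 t at 1.4 t/ha but only
+14,691,829 t at 0.4 t/ha), which is exactly the uncertainty the
two-bound account is designed to expose.

A fully synthetic run, from scenario to accounts on disk:

```r
cfg <- list(seed = 7, scenario = list(eu25_toy = TRUE, n_samples = 2000))
run_simulate(cfg, out_dir = "out", seed = 7)
run_extent(cfg, out_dir = "out")     # extent_2000_2012.csv, net summaries
run_condition(cfg, out_dir = "out")  # SOC and pH cross-tabs per epoch
```

## Package layout

| Area | Entry points |
|---|---|
| Classes & mapping | `seea_classes()`, `read_class_mapping()` |
| Grids | `land_cover_grid()`, `read_grid()`, `write_grid()`, `aggregate_classes()`, `area_by_class()` |
| Extent | `change_matrix()`, `build_extent_account()`, `net_change_summary()`, `write_extent_account()` |
| Mass | `formation_rates()`, `erosion_params()`, `partition_erosion()`, `build_mass_account()`, `net_balance_summary()`, `write_mass_account()` |
| Condition | `peat_mask()`, `classify_soc()`, `classify_ph()`, `condition_crosstab()`, `change_condition_crosstab()` |
| Synthetic | `scenario()`, `eu25_toy_scenario()`, `gen_initial_grid()`, `advance_epoch()`, `gen_soil_samples()`, `recover_transitions()` |
| Pipeline | `run_simulate()`, `run_extent()`, `run_mass()`, `run_condition()`, `inst/cli/soilcap.R` |
| EU-25 inputs | `eu_extent_inputs()`, `eu_extent_account()`, `eu_mass_inputs()`, `eu_mass_account()` |

The methods vignette (`vignettes/soil-accounts.Rmd`) documents the
model, parameter defaults, boundary conventions, the synthetic
generator's scope, and known limitations.
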