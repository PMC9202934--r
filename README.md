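# hmrisk

Probabilistic dietary risk assessment of heavy metals in
wastewater-irrigated vegetables.

Untreated industrial wastewater is widely reused for irrigation in
water-scarce regions. Heavy metals (Fe, Pb, Cr, Ni, Mn, Co) accumulate in
the irrigated soil, transfer into the edible parts of vegetables, and
reach consumers through the diet. `hmrisk` implements the standard
assessment chain for this exposure route, for risk assessors and
environmental-health researchers:

- **Metal transfer factor** — the soil-to-plant accumulation ratio

  MTF = C_plant / C_soil

  (dry-weight concentrations, same irrigation source; MTF > 1 flags net
  accumulation in the plant).

- **Estimated daily intake** (mg metal / kg body weight / day)

  EDI = (C × C_f × EF × ED × IR) / (BW × AT)

  with C the dry-weight concentration in the vegetable (mg/kg), C_f the
  fresh-to-dry conversion factor (0.085), EF the exposure frequency
  (days/year), ED the exposure duration (years), IR the fresh-weight
  ingestion rate (kg/day), BW the body weight (kg) and AT the averaging
  time (days; by default ED × 365).

- **Target hazard quotient and hazard index**

  THQ = EDI / RfD,  HI = Σ THQ

  where RfD is the oral reference dose. HI sums THQ over the six metals
  and the four vegetables of the assessed diet; HI < 1 is read as "no
  appreciable non-carcinogenic risk".

Uncertainty in every input (lognormal concentrations, zero-truncated
normal ingestion rates, triangular exposure frequency, uniform exposure
duration, lognormal body weight) is propagated with a seeded Monte Carlo
engine. Forecasts are summarized with percentile statistics, convergence
is checked between independent runs, and output variance is attributed to
the inputs by normalized squared Spearman rank correlations
("contribution to variance"). Field concentration tables for
industrial-wastewater (IWW) and tube-well (TWW) irrigation ship with the
package, and a synthetic-data generator with known ground truth supports
validation end to end.

## Worked example

```r
library(hmrisk)

soil <- load_concentration_table(hmrisk_example("soil.csv"))
veg  <- load_concentration_table(hmrisk_example("vegetables_iww.csv"))

# Which vegetable/metal pairs accumulate under IWW irrigation?
mtf <- compute_mtf(veg, soil, "IWW")
subset(mtf, mtf > 1)
#>       vegetable metal   mtf
#> 2    Ladyfinger    Pb 1.202
#> 11      Pumpkin    Mn 1.078
#> 20 Green pepper    Pb 1.226

cfg <- default_risk_config("IWW")
point_risk_assessment(veg, cfg, "adults")
#> <exposure_result> group adults, source IWW
#> HI by vegetable:
#>   Ladyfinger      Pumpkin        Onion Green pepper
#>     0.057550     0.034570     0.004571     0.021740
#> HI total: 0.1184 (below the safety threshold of 1)

sim <- run_simulation(veg, cfg, "adults", n_iter = 10000, seed = 42)
sim
#> <simulation_result> adults/IWW, 10000 iterations (seed 42)
#> <summary_stats>
#>      mean        sd  variance   minimum   maximum        p5       p50
#> 0.1035000 0.0227300 0.0005167 0.0431100 0.2070000 0.0686500 0.1022000
#>       p90       p95
#> 0.1336000 0.1429000

sens <- contribution_to_variance(sim$inputs, sim$hi_total)
pool_contributions(sens, "^IR\\.")
#> [1] 29.9
```

Only three vegetable/metal pairs show net soil-to-plant accumulation
(lead in ladyfinger and green pepper, manganese in pumpkin). The adult
hazard index from the IWW diet centres near 0.10 — an order of magnitude
below the safety threshold of 1 — and about 30% of its variance traces
back to the ingestion-rate assumptions for this group (most of the rest
comes from the exposure-frequency spread).

`run_full_pipeline()` chains every stage (validation, MTF, point
estimate, simulation, sensitivity, convergence) for all groups and
sources and writes a reproducible report bundle; a thin command-line
wrapper lives at `inst/scripts/hmrisk.R`.

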