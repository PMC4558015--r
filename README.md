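# csaccess

Coverage and location-allocation analysis of free caesarean-section (C-section)
services, for health planners and analysts asking two questions about a
district: *which villages can already reach a facility that performs free
C-sections within a reasonable emergency travel distance*, and *which
facilities should be upgraded or contracted next to close the gaps*.

C-section is the standard proxy for access to comprehensive emergency
obstetric care; in settings where much of the surgical capacity is private,
programmes that contract private obstetricians to provide free care turn
facility placement into a solvable geographic optimization. `csaccess`
implements that analysis as a reusable, fully tested pipeline, exercised
end to end on synthetic geography so that no restricted census, survey or
road data are needed.

## The model

* **Demand.** For village *v* with population *P_v* in a block with crude
  birth rate CBR_b (births/1000/year): annual births
  *X_v = (CBR_b / 1000) · P_v*, daily births *Y_v = X_v / 365*, and
  obstetric bed-day demand *D_v = Y_v (0.85·2 + 0.15·5) = 2.45 Y_v*
  bed-days/day (15% of births complicated with a 5-day stay, 2 days
  otherwise). Capacity comparisons use the annualized *365 D_v = 2.45 X_v*.
* **Supply.** A facility provides `obstetric_beds × 365` bed-days/year.
  Facilities classify as *supply centres* (currently provide free
  C-sections), *candidate centres* (contractable private or upgradable
  public facilities) or *excluded*; nearby supply centres within 1 km merge
  to the highest-capacity one.
* **Catchments.** Distances are shortest paths along the road network
  (Dijkstra, planar km); a village is covered if an open facility lies
  within 20 km (≈ 1 hour of ambulance travel), boundary inclusive.
* **Allocation.** The current scenario opens all supply centres; the
  improvement scenario greedily adds the candidate with the largest
  marginal covered population (a maximal-covering heuristic with a
  demand-weighted-distance tie-break) until the best gain falls below one
  percentage point. Each open facility is classified *under* or *over*
  capacity by comparing served bed-day demand with its bed-day supply.

An exhaustive subset enumerator (`exact_best_subset()`) serves as a
small-instance optimality oracle for the greedy heuristic, and
`plant_coverage_gap()` builds synthetic regions with a known uncovered
cluster and a unique correct answer for validation.

## Worked example

```r
library(csaccess)
spec <- region_spec(n_blocks = 6, villages_per_block = c(12, 18),
                    total_population = 3e5, n_supply_centers = 12,
                    n_candidates = 6, extent_km = 60, seed = 3)
region <- generate_region(spec)
region
#> <region> 94 villages in 6 blocks, 18 facilities, 161 road segments, 60 km extent, pop 3e+05

scenario <- build_scenario(region, cutoff_km = 20, stop_threshold = 1)
before <- solve_current(scenario)
before
#> <allocation_result> 12 open facilities, 289,677 of 3e+05 covered (96.6%), 0 under / 12 over capacity

after <- greedy_add_candidates(scenario)
after
#> <allocation_result> 14 open facilities, 299,641 of 3e+05 covered (99.9%), 1 under / 13 over capacity
#>   added: F013 (98.3%), F018 (99.9%)
```

Reading this: with the 12 existing supply centres, 289,677 of 300,000
people (96.6%) live within 20 road-km of free C-section care, and every
centre has enough bed-days for the demand it serves. Adding candidates one
by one, facility F013 gains the most uncovered population (coverage rises
to 98.3%), then F018 (99.9%); the next-best candidate would add less than
one percentage point, so the procedure stops. One of the 14 open centres
now serves more bed-day demand than its beds supply ("under capacity") —
coverage and capacity are reported separately, because being within reach
of a centre does not guarantee the centre has a free bed.

`summarize_allocation(before, after, "district")` condenses this into a
one-row district table (populations in millions, half-up integer
percentages, under/over capacity counts before and after).

## Analysis workflow

The `analysis/` scripts run the full study pipeline on three simulated
districts whose populations and supply-centre counts mirror a published
three-district study setting, writing all layers and tables under
`results/` (regenerated on each run; not versioned):

```sh
Rscript analysis/01_simulate.R      # synthetic districts -> GeoJSON/CSV layers
Rscript analysis/02_demand_supply.R # demand.csv, facilities_classified.csv
Rscript analysis/03_allocate.R      # allocation, trajectory, coverage.geojson
Rscript analysis/04_report.R        # results/summary.csv
```

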