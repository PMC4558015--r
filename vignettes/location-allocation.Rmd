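---
title: "Coverage and location-allocation of free C-section services: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage and location-allocation of free C-section services: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaccess)
```

## The problem

Caesarean section is the canonical proxy for access to comprehensive
emergency obstetric care (CEmOC): where a complicated delivery cannot reach
a facility able to perform one within roughly two hours, maternal and
perinatal mortality rise sharply. In rural India much of the C-section
capacity sits in the private sector, so several states contract private
obstetricians to deliver free intrapartum care to poor mothers; planning
then turns into a geographic question — *which villages can already reach a
free C-section centre, and where should additional centres be opened or
contracted first?*

`csaccess` answers that question as a location-allocation pipeline over
four ingredients: village points with populations, block-level crude birth
rates, facility points with obstetric bed counts and programme attributes,
and a road network. Because the census, facility-survey and digitized road
data such an analysis runs on are not generally redistributable, the
package ships a synthetic geography generator that emulates their
structure, making every stage testable end to end.

## Demand: obstetric bed-days required

For village $v$ with population $P_v$ in a block with crude birth rate
$\mathrm{CBR}_b$ (births per 1000 population per year), expected births are

$$X_v = \frac{\mathrm{CBR}_b}{1000}\,P_v \quad\text{births/year},\qquad
  Y_v = X_v / 365 \quad\text{births/day}.$$

A fixed 15% of births are assumed complicated (the WHO planning
assumption); normal deliveries occupy an obstetric bed for 2 days (the
Indian federal norm) and complicated ones for 5 days, so bed-day demand is

$$D_v = Y_v\,(0.85\cdot 2 + 0.15\cdot 5) = 2.45\,Y_v
  \quad\text{bed-days/day}.$$

All three constants are exposed as arguments of `bed_days_demand()` but the
defaults are the published model. Births are never rounded to integers:
demand is an expectation, and rounding would break the linearity the tests
rely on (`demand(2P) = 2\,demand(P)`).

**Units.** $D_v$ is a per-day quantity while facility supply is annual
(beds × 365). Comparing the two directly would be dimensionally
inconsistent, so every capacity comparison in this package uses the
annualized demand $365\,D_v = 2.45\,X_v$ bed-days/year. A per-1000
normalization (`demand_per_1000()`) is available for reporting only; the
under/over-capacity rule always compares totals, since that is the only
reading under which the published under/over classifications are coherent.

## Supply, roles, and the competing-centre merge

A facility's annual supply is `obstetric_beds * 365` bed-days. Roles:

* **supply centre** — currently provides free C-sections: public and
  performing C-sections, or private, programme-enrolled and performing
  C-sections;
* **candidate centre** — could be operationalized: private with C-section
  capability but not enrolled (contractable), or public with basic
  obstetric care but no C-section capability (upgradable);
* **excluded** — private without C-section capability.

Supply centres "close to each other" compete for one catchment; within each
single-linkage group of centres pairwise closer than `epsilon_km` (network
distance) only the highest-capacity centre is retained, ties going to the
smaller facility id. The published account gives no number for "close", so
the default is 1 km — about one town — and the merge can be disabled
(`merge = FALSE`), since treating co-located capacity as redundant is
itself a modelling simplification. No minimum bed count is imposed on
public candidates; the role definitions say nothing about one.

## Network distances and catchments

Coordinates are planar kilometres in a local projected frame, so Euclidean
segment lengths are exact and no geodesy is involved. Road endpoints within
10⁻⁶ km fuse into graph nodes; each village or facility attaches to its
nearest node through a connector equal to its Euclidean offset, which keeps
distances exact down to the last mile (an entity 0.1 km off the road adds
0.1 km to every route). Offsets beyond `snap_tolerance_km` (default 2 km)
are flagged for QC but still attached, so reachability is guaranteed.
Shortest paths are Dijkstra's algorithm via `igraph`; the test suite checks
them against an independent brute-force enumeration of all simple paths on
small random graphs.

The catchment cutoff defaults to 20 km of *network* distance — the distance
an ambulance covers in about one hour on sub-district roads, and one hour is
the accepted decision-plus-transport budget inside the two-hour
complication-to-care window. Network rather than straight-line distance is
used because the distances in the source analysis were measured along the
road network; a Euclidean mode (`metric = "euclidean"`) exists for
sensitivity analysis. The boundary is inclusive (`<= 20` km): the published
convention is unstated, and exclusivity would drop villages at
digitization-noise distance from the boundary.

## Allocation: current scenario and incremental addition

`solve_current()` opens every retained supply centre. Each village with an
open facility within the cutoff is assigned to the *nearest* one (ties:
larger capacity, then smaller id); covered population is the sum over
assigned villages, and coverage is reported as a percentage of district
population.

`greedy_add_candidates()` mirrors the incremental procedure of adding
candidate centres one at a time: at each step it opens the candidate with
the largest marginal covered population, stopping when the best gain drops
below `stop_threshold` percentage points of the district population
(default 1 point), when `max_additions` is reached, or when candidates run
out. The trajectory of (added centre, coverage) pairs is retained. The
demand-weighted distance objective of the p-median flavour enters only as a
tie-break among equal-coverage candidates — coverage is lexicographically
prior — because the source procedure reports its choices purely through
coverage gained. A 1-point threshold reproduces the "a handful of additions,
then flat" behaviour on district-scale synthetic instances and is
configurable.

**Coverage vs capacity.** Coverage counts villages by distance only;
capacity classifies each open facility as *under* (supply strictly less
than served demand) or *over* (supply equal or greater) but never
un-covers villages. This is the only reading consistent with a district
being reported near-fully covered while all its centres are under
capacity. A strictly capacitated assignment (`capacitated = TRUE`), in
which demand above capacity spills to the next-nearest open facility
within the cutoff, is provided for the alternative reading.

`exact_best_subset()` enumerates all candidate subsets of a given size
(guarded at 10⁵ subsets) and exists purely as a small-instance oracle for
the greedy heuristic; greedy coverage can never exceed it, and the tests
assert exactly that on dozens of random instances.

## The synthetic geography

`generate_region()` draws block centres on a jittered grid, villages
around them (truncated Gaussian scatter), village populations from a
log-normal (sdlog 0.8) rescaled by largest-remainder rounding to the exact
requested total — Indian village sizes are heavy-tailed, and no published
distribution exists to calibrate against, so the family and dispersion are
stated assumptions — one CBR per block uniform in `cbr_range`, facilities
at population-weighted villages with role-consistent attributes, and a
road network that is connected by construction: either a Euclidean
minimum-spanning-tree backbone over settlements with nearest-neighbour
shortcuts (`random-planar`, the default) or a regular 5 km grid (`grid`).
The spec defaults (12 blocks of 90–100 villages, 2 M people, 15–30 CBR,
0–30 beds, 80 km extent) emulate one study-scale district.

What the generator does *not* emulate: real road hierarchies and travel
speeds, rivers and terrain barriers, clustered poverty, or correlation
between facility size and town size. Passing tests therefore demonstrate
correctness of the *method* under structurally realistic inputs, not
calibration to any real district.

`plant_coverage_gap()` builds ground truth for validation: it picks a
northern-belt village whose 20 km network neighbourhood holds the most
population, accumulates villages around it (never beyond the cutoff, so
one centre at the seed can cover the whole cluster) until the requested
population share is reached, relocates or drops supply centres that reach
the cluster, moves one candidate to the seed, and co-locates every other
candidate with a retained supply centre so its marginal gain is exactly
zero. The planted candidate is then the unique improving move, and the
greedy procedure must find it first — asserted over 20 seeds in the tests.

## Numerical and reporting choices

* **Rounding**: reported percentages use round-half-up to integers
  (`round_half_up()`), the rule that reproduces every verifiable printed
  coverage cell from its printed inputs; populations are reported in
  millions at 2 decimals. Published cells that cannot be reproduced from
  any rounding of their printed inputs are treated as artefacts of
  unprinted unrounded values and are not asserted.
* **Tie-breaks** are total and deterministic everywhere (capacity then id
  for assignment; weighted distance then id for greedy; lexicographic for
  the enumerator), so a fixed seed makes the whole pipeline byte-identical
  across runs.
* **Degenerate inputs**: zero supply centres give 0% coverage rather than
  an error; empty regions give empty tables; an empty road layer, unknown
  ids, missing layers and broken block references raise named errors.
* **Problem sizes**: unit and property tests run on hand-built line
  regions and 9–10-village random regions; the planted-gap suite uses
  six-block regions of 12–18 villages (300 k people, 60 km frame); the
  analysis scripts and acceptance run use full district scale
  (~1100 villages, 2 M people). These sizes were chosen so the exhaustive
  oracles stay exact and the whole suite runs in well under a minute.

## Limitations

The analysis is bounded by the district frame: no demand crosses the
boundary in either direction, which the source analysis itself flags as a
limitation. Travel time is represented only through the 20 km cutoff — no
road-class speeds, elevation or one-way restrictions. Facility quality,
staffing and payment mechanics are out of scope; beds are the sole capacity
currency. And the competing-centre merge discards co-located capacity that
could in reality serve demand jointly, which is why it is optional.
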