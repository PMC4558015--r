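#!/usr/bin/env Rscript
# Step 1 — simulate three synthetic districts.
#
# Each district mirrors the scale of one real study district: total
# population and current supply-centre count follow the published district
# table (2.12 M / 8, 2.42 M / 23, 1.75 M / 18), with 10 candidate centres
# apiece, 12 blocks of 90-100 villages, block CBRs in 15-30 per 1000, and a
# connected settlement-to-settlement road network in an 80 km planar frame.
# Layers are written as GeoJSON/CSV under results/regions/<district>/.

suppressPackageStartupMessages(library(csaccess))

districts <- list(
  `district-A` = list(pop = 2.12e6, supply = 8,  seed = 101L),
  `district-B` = list(pop = 2.42e6, supply = 23, seed = 102L),
  `district-C` = list(pop = 1.75e6, supply = 18, seed = 103L))

for (name in names(districts)) {
  d <- districts[[name]]
  spec <- region_spec(n_blocks = 12, villages_per_block = c(90, 100),
                      total_population = d$pop, cbr_range = c(15, 30),
                      n_supply_centers = d$supply, n_candidates = 10,
                      bed_range = c(0, 30), extent_km = 80, seed = d$seed)
  region <- generate_region(spec)
  out <- file.path("results", "regions", name)
  write_region(region, out)
  cat(sprintf("%s: %d villages, %d facilities, pop %s -> %s\n",
              name, nrow(region$villages), nrow(region$facilities),
              format(sum(region$villages$population), big.mark = ","), out))
}
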