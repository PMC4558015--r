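#!/usr/bin/env Rscript
# Step 2 — village demand and facility classification.
#
# For each simulated district: evaluate the obstetric bed-day demand chain
# (annual births from block CBR and population, daily births, bed-days at
# 85%/15% normal/complicated with 2/5-day stays, annualized), and classify
# facilities into supply / candidate / excluded with their annual bed-day
# capacity.  Writes demand.csv and facilities_classified.csv per district.

suppressPackageStartupMessages(library(csaccess))

for (dir in list.dirs(file.path("results", "regions"), recursive = FALSE)) {
  region <- read_region(dir)
  dem <- demand_per_1000(village_demand_table(region))
  write.csv(dem[, c("village_id", "population", "cbr", "births_per_year",
                    "births_per_day", "bed_days_per_year",
                    "bed_days_per_year_per_1000")],
            file.path(dir, "demand.csv"), row.names = FALSE)
  fac <- classify_facilities(region)
  write.csv(fac[, c("facility_id", "sector", "performs_csection",
                    "cy_enrolled", "role", "obstetric_beds",
                    "bed_days_per_year")],
            file.path(dir, "facilities_classified.csv"), row.names = FALSE)
  cat(sprintf("%s: demand %.0f bed-days/yr over %d villages; %d supply, %d candidate, %d excluded\n",
              basename(dir), sum(dem$bed_days_per_year), nrow(dem),
              sum(fac$role == "supply"), sum(fac$role == "candidate"),
              sum(fac$role == "excluded")))
}
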