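#!/usr/bin/env Rscript
# Step 4 — district summary table.
#
# Assembles the before/after coverage summary (populations in millions,
# half-up integer percentages, under/over-capacity centre counts) for the
# three simulated districts into results/summary.csv, the synthetic analogue
# of a published district coverage table.

suppressPackageStartupMessages(library(csaccess))

rows <- list()
for (dir in list.dirs(file.path("results", "allocation"),
                      recursive = FALSE)) {
  rows[[basename(dir)]] <- read.csv(file.path(dir, "district_summary.csv"))
}
summary <- do.call(rbind, rows)
write.csv(summary, file.path("results", "summary.csv"), row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nwrote results/summary.csv\n")
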