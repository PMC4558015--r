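# Hand-built regions for unit tests.  All coordinates are planar km.

# assemble a region object directly from its component tables
make_region <- function(villages, blocks, facilities, roads,
                        extent_km = 100, snap_tolerance_km = 2, seed = 0L) {
  structure(list(villages = villages, blocks = blocks,
                 facilities = facilities, roads = roads,
                 extent_km = extent_km,
                 snap_tolerance_km = snap_tolerance_km, seed = seed),
            class = "region")
}

# villages and facilities strung along a straight east-west road at y = 0,
# so every network distance is just |x_i - x_j|
line_region <- function(village_x, village_pop, facility_x, facility_attrs,
                        cbr = 25) {
  nv <- length(village_x)
  xs <- sort(unique(c(village_x, facility_x, 0)))
  roads <- data.frame(
    road_id = sprintf("R%03d", seq_len(length(xs) - 1)),
    x1 = xs[-length(xs)], y1 = 0, x2 = xs[-1], y2 = 0,
    length_km = diff(xs), stringsAsFactors = FALSE)
  villages <- data.frame(
    village_id = sprintf("V%02d", seq_len(nv)),
    name = sprintf("v%02d", seq_len(nv)),
    block_id = "B01", x_km = village_x, y_km = 0,
    population = village_pop, stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = "B01", cbr_per_1000 = cbr,
                       stringsAsFactors = FALSE)
  facilities <- cbind(
    data.frame(facility_id = sprintf("F%02d", seq_along(facility_x)),
               x_km = facility_x, y_km = 0, stringsAsFactors = FALSE),
    facility_attrs)
  make_region(villages, blocks, facilities, roads,
              extent_km = max(xs) - min(xs) + 1)
}

# facility attribute block: n supply centres then m candidates
fac_attrs <- function(n_supply, n_candidate, beds = 10) {
  n <- n_supply + n_candidate
  data.frame(
    sector = rep(c("public", "private"), c(n_supply, n_candidate)),
    performs_csection = rep(c(TRUE, TRUE), c(n_supply, n_candidate)),
    cy_enrolled = rep(FALSE, n),
    obstetric_beds = rep(beds, length.out = n),
    stringsAsFactors = FALSE)
}

# small random region spec used across property tests
small_spec <- function(seed, n_candidates = 4) {
  region_spec(n_blocks = 2, villages_per_block = c(4, 5),
              total_population = 5e4, cbr_range = c(15, 30),
              n_supply_centers = 1, n_candidates = n_candidates,
              bed_range = c(1, 10), extent_km = 45, seed = seed)
}

# the study-conditions planted-gap instance (scaled to one small district)
gap_spec <- function(seed) {
  region_spec(n_blocks = 6, villages_per_block = c(12, 18),
              total_population = 3e5, cbr_range = c(15, 30),
              n_supply_centers = 12, n_candidates = 6,
              bed_range = c(0, 30), extent_km = 60, seed = seed)
}
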