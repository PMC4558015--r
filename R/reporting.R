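#' Integer coverage percentage
#'
#' `round_half_up(covered / total * 100)`, the rounding that reproduces the
#' published district coverage cells from their printed covered/total
#' population pairs.
#'
#' @param covered covered population (persons, or any consistent unit).
#' @param total total population (> 0, same unit).
#' @return integer percent.
#' @export
pct <- function(covered, total) {
  check_nonneg(covered, "covered")
  if (!is.numeric(total) || any(total <= 0)) {
    stop("'total' must be > 0", call. = FALSE)
  }
  if (any(covered > total)) {
    stop("'covered' must not exceed 'total'", call. = FALSE)
  }
  round_half_up(covered / total * 100)
}

#' District summary of a before/after allocation pair
#'
#' One summary row in the shape of a published district coverage table:
#' populations in millions at two decimals, integer coverage percentages
#' (half-up rounding of the unrounded ratios), the percentage-point increase
#' computed from unrounded covered populations, and under/over capacity
#' centre counts before and after allocation.
#'
#' @param before `allocation_result` of the current scenario.
#' @param after `allocation_result` after incremental candidate addition.
#' @param district_name district label for the row.
#' @return a one-row data frame (`district_summary`).
#' @export
summarize_allocation <- function(before, after, district_name = "district") {
  stopifnot(inherits(before, "allocation_result"),
            inherits(after, "allocation_result"))
  if (before$total_population != after$total_population ||
      !all(before$open_facilities %in% after$open_facilities)) {
    stop("'before' and 'after' do not come from the same scenario",
         call. = FALSE)
  }
  total <- before$total_population
  n_added <- length(setdiff(after$open_facilities, before$open_facilities))
  data.frame(
    district = district_name,
    total_population_millions = round_half_up(total / 1e6, 2),
    n_supply = length(before$open_facilities),
    covered_current_millions = round_half_up(before$covered_population / 1e6, 2),
    pct_current = pct(before$covered_population, total),
    n_candidates_added = n_added,
    covered_after_millions = round_half_up(after$covered_population / 1e6, 2),
    pct_after = pct(after$covered_population, total),
    pct_point_increase = round_half_up(
      (after$covered_population - before$covered_population) / total * 100),
    n_under_before = sum(before$capacity_status == "under"),
    n_over_before = sum(before$capacity_status == "over"),
    n_under_after = sum(after$capacity_status == "under"),
    n_over_after = sum(after$capacity_status == "over"),
    stringsAsFactors = FALSE)
}

#' Write allocation outputs as CSV tables
#'
#' Writes `allocation.csv` (village assignments), `facilities_out.csv`
#' (roles, loads, capacity statuses) and `trajectory.csv` (incremental
#' additions) into a directory.
#'
#' @param scenario the `scenario` the result came from.
#' @param result an `allocation_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_allocation_tables <- function(scenario, result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alloc <- result$assignment
  names(alloc)[names(alloc) == "facility_id"] <- "assigned_facility_id"
  p1 <- file.path(dir, "allocation.csv")
  utils::write.csv(alloc, p1, row.names = FALSE)

  f <- scenario$facilities
  f$opened <- f$facility_id %in% result$open_facilities
  f$load <- ifelse(f$opened, result$facility_loads[f$facility_id], NA)
  f$supply_bed_days <- f$bed_days_per_year
  f$capacity_status <- ifelse(f$opened,
                              result$capacity_status[f$facility_id], NA)
  p2 <- file.path(dir, "facilities_out.csv")
  utils::write.csv(f[, c("facility_id", "role", "merged_into", "opened",
                         "load", "supply_bed_days", "capacity_status")],
                   p2, row.names = FALSE)

  p3 <- file.path(dir, "trajectory.csv")
  utils::write.csv(result$trajectory, p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Export coverage as GeoJSON
#'
#' Writes a FeatureCollection of village points tagged `covered` (and the
#' assigned facility) and facility points tagged `role`, `opened` and
#' `capacity_status`, for mapping.  Coordinates are in the region's planar
#' km frame.
#'
#' @param region the `region`.
#' @param result an `allocation_result` for that region.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_coverage_geojson <- function(region, result, path) {
  stopifnot(inherits(region, "region"), inherits(result, "allocation_result"))
  a <- result$assignment
  v <- region$villages
  vi <- match(v$village_id, a$village_id)
  vill_feats <- lapply(seq_len(nrow(v)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(v$x_km[i], v$y_km[i])),
         properties = list(kind = "village", id = v$village_id[i],
                           population = v$population[i],
                           covered = isTRUE(a$covered[vi[i]]),
                           assigned_facility_id =
                             if (is.na(a$facility_id[vi[i]])) NULL
                             else a$facility_id[vi[i]]))
  })
  f <- classify_facilities(region)
  fac_feats <- lapply(seq_len(nrow(f)), function(i) {
    fid <- f$facility_id[i]
    opened <- fid %in% result$open_facilities
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(f$x_km[i], f$y_km[i])),
         properties = list(kind = "facility", id = fid, role = f$role[i],
                           opened = opened,
                           capacity_status =
                             if (opened) unname(result$capacity_status[fid])
                             else NULL))
  })
  fc <- list(type = "FeatureCollection", features = c(vill_feats, fac_feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
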