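#' Assemble a location-allocation scenario
#'
#' Pulls together everything one allocation run needs: the per-village demand
#' table, classified facilities with annual bed-day capacities, the
#' competing-centre merge among supply centres (nearby centres compete for
#' the same catchment; only the highest-capacity one is kept), and the
#' village-to-facility network distance matrix truncated at the catchment
#' cutoff.
#'
#' @param region a `region`.
#' @param cutoff_km catchment cutoff in km (default 20, the distance an
#'   ambulance covers in about one hour on Indian sub-district roads).
#' @param stop_threshold minimum coverage gain, in percentage points of the
#'   total population, for the incremental procedure to keep adding centres
#'   (default 1).
#' @param max_additions cap on the number of candidate centres added.
#' @param merge apply the competing-centre merge to supply centres
#'   (default `TRUE`; the merge mirrors how the allocation software treats
#'   near-duplicate supply sites and can be disabled).
#' @param epsilon_km competing-centre merge radius in km.
#' @param metric `"network"` (road distance, the default) or `"euclidean"`
#'   (straight-line, for sensitivity analysis).
#' @param capacitated if `TRUE`, village assignment respects bed-day
#'   capacities: demand above a facility's capacity spills to the
#'   next-nearest open facility within the cutoff (see [assign_villages()]).
#'   Coverage accounting by distance only is the default reading.
#' @param snap_tolerance_km road-snap tolerance; defaults to the region's.
#' @return a `scenario` object.
#' @export
build_scenario <- function(region, cutoff_km = 20, stop_threshold = 1,
                           max_additions = Inf, merge = TRUE,
                           epsilon_km = 1,
                           metric = c("network", "euclidean"),
                           capacitated = FALSE,
                           snap_tolerance_km = NULL) {
  stopifnot(inherits(region, "region"))
  metric <- match.arg(metric)
  check_nonneg(cutoff_km, "cutoff_km")
  check_nonneg(stop_threshold, "stop_threshold")

  demand <- village_demand_table(region)
  fac <- classify_facilities(region)
  fac <- fac[fac$role != "excluded", , drop = FALSE]
  fac$merged_into <- ""

  v <- region$villages
  if (metric == "network") {
    rg <- region_graph(region, snap_tolerance_km)
    dm <- shortest_distances(rg, v$village_id, fac$facility_id, cutoff_km)
    if (merge && sum(fac$role == "supply") > 1) {
      sup <- fac[fac$role == "supply", , drop = FALSE]
      fd <- shortest_distances(rg, sup$facility_id, sup$facility_id)$km
      mg <- merge_competing_centers(sup, fd, epsilon_km)
      fac$merged_into <- ifelse(fac$facility_id %in% names(mg$merged_into),
                                mg$merged_into[fac$facility_id], "")
    }
  } else {
    km <- outer(seq_len(nrow(v)), seq_len(nrow(fac)), function(i, j) {
      euclid(v$x_km[i], v$y_km[i], fac$x_km[j], fac$y_km[j])
    })
    dimnames(km) <- list(v$village_id, fac$facility_id)
    km[km > cutoff_km] <- Inf
    dm <- structure(list(km = km, cutoff_km = cutoff_km),
                    class = "distance_matrix")
    if (merge && sum(fac$role == "supply") > 1) {
      sup <- fac[fac$role == "supply", , drop = FALSE]
      fd <- as.matrix(stats::dist(sup[, c("x_km", "y_km")]))
      dimnames(fd) <- list(sup$facility_id, sup$facility_id)
      mg <- merge_competing_centers(sup, fd, epsilon_km)
      fac$merged_into <- ifelse(fac$facility_id %in% names(mg$merged_into),
                                mg$merged_into[fac$facility_id], "")
    }
  }

  structure(list(villages = v, demand = demand, facilities = fac,
                 distances = dm, cutoff_km = cutoff_km,
                 stop_threshold = stop_threshold,
                 max_additions = max_additions,
                 capacitated = capacitated,
                 total_population = sum(v$population)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(paste0("<scenario> %d villages, %d supply (%d retained after ",
                     "merge), %d candidates, cutoff %.0f km\n"),
              nrow(x$villages), sum(x$facilities$role == "supply"),
              sum(x$facilities$role == "supply" & x$facilities$merged_into == ""),
              sum(x$facilities$role == "candidate"), x$cutoff_km))
  invisible(x)
}

# supply-role facilities that survived the competing-centre merge
retained_supply <- function(scenario) {
  f <- scenario$facilities
  f$facility_id[f$role == "supply" & f$merged_into == ""]
}

#' Assign villages to open facilities
#'
#' Each village with at least one open facility within the cutoff is assigned
#' to the nearest such facility; ties go to the larger-capacity facility,
#' then to the smaller facility id.  Other villages remain unassigned.  In
#' capacitated mode villages are processed in order of increasing distance to
#' their nearest open facility and take the nearest open facility within the
#' cutoff that still has enough free annual bed-day capacity for the whole
#' village demand; a village that fits nowhere falls back to its nearest open
#' facility (coverage is by distance; capacity shows up as overload).
#'
#' @param scenario a `scenario`.
#' @param open_set character vector of open facility ids (subset of the
#'   scenario's supply and candidate facilities).
#' @return data frame: `village_id`, `facility_id` (NA if unassigned),
#'   `distance_km`, `covered`.
#' @export
assign_villages <- function(scenario, open_set) {
  stopifnot(inherits(scenario, "scenario"))
  f <- scenario$facilities
  bad <- setdiff(open_set, f$facility_id)
  if (length(bad) > 0) {
    stop(sprintf("open_set contains unknown facility id(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  v_ids <- scenario$villages$village_id
  out <- data.frame(village_id = v_ids, facility_id = NA_character_,
                    distance_km = NA_real_, covered = FALSE,
                    stringsAsFactors = FALSE)
  if (length(open_set) == 0 || length(v_ids) == 0) return(out)

  km <- scenario$distances$km[, open_set, drop = FALSE]
  cap <- setNames(f$bed_days_per_year, f$facility_id)[open_set]
  # tie-break ordering of columns: capacity desc, then id asc
  col_ord <- order(-cap, open_set)
  km_o <- km[, col_ord, drop = FALSE]
  ids_o <- open_set[col_ord]

  nearest_j <- apply(km_o, 1, which.min)
  nearest_d <- km_o[cbind(seq_len(nrow(km_o)), nearest_j)]
  reachable <- is.finite(nearest_d) & nearest_d <= scenario$cutoff_km

  if (!isTRUE(scenario$capacitated)) {
    out$facility_id[reachable] <- ids_o[nearest_j[reachable]]
    out$distance_km[reachable] <- nearest_d[reachable]
    out$covered <- reachable
    return(out)
  }

  # capacitated: fill facilities nearest-first, spill overflow
  dem <- setNames(scenario$demand$bed_days_per_year,
                  scenario$demand$village_id)[v_ids]
  free <- cap[ids_o]
  for (i in order(nearest_d)) {
    if (!reachable[i]) next
    opts <- which(is.finite(km_o[i, ]))
    opts <- opts[order(km_o[i, opts], -free[opts])]
    fits <- opts[free[opts] >= dem[i]]
    j <- if (length(fits) > 0) fits[1] else opts[1]
    out$facility_id[i] <- ids_o[j]
    out$distance_km[i] <- km_o[i, j]
    out$covered[i] <- TRUE
    free[j] <- free[j] - dem[i]
  }
  out
}

#' Facility loads from an assignment
#'
#' The load on a facility is the sum of annual bed-day demand of all
#' villages assigned to it.
#'
#' @param assignment output of [assign_villages()].
#' @param demands output of [village_demand_table()].
#' @return named numeric vector, facility id -> bed-days per year (only
#'   facilities with at least one assigned village appear unless `open_set`
#'   is given via names; use [solve_current()] for zero-load facilities).
#' @export
facility_load <- function(assignment, demands) {
  a <- assignment[!is.na(assignment$facility_id), , drop = FALSE]
  dem <- setNames(demands$bed_days_per_year, demands$village_id)
  if (nrow(a) == 0) return(setNames(numeric(0), character(0)))
  tl <- tapply(dem[a$village_id], a$facility_id, sum)
  setNames(as.numeric(tl), names(tl))
}

#' Classify a facility's capacity status
#'
#' A centre is *under* capacity when its annual bed-day supply is strictly
#' less than the demand it serves, and *over* capacity when supply is enough
#' or more than demand (equality counts as over).
#'
#' @param load served demand, bed-days per year (>= 0).
#' @param supply available bed-days per year (>= 0).
#' @return character vector, `"under"` or `"over"`.
#' @export
capacity_status <- function(load, supply) {
  check_nonneg(load, "load")
  check_nonneg(supply, "supply")
  ifelse(supply < load, "under", "over")
}

# evaluate an open set: assignment, loads, statuses, coverage
evaluate_open_set <- function(scenario, open_set) {
  assignment <- assign_villages(scenario, open_set)
  pop <- setNames(scenario$villages$population, scenario$villages$village_id)
  covered_pop <- sum(pop[assignment$covered])
  loads <- setNames(rep(0, length(open_set)), open_set)
  got <- facility_load(assignment, scenario$demand)
  loads[names(got)] <- got
  caps <- setNames(scenario$facilities$bed_days_per_year,
                   scenario$facilities$facility_id)[open_set]
  structure(list(open_facilities = open_set,
                 assignment = assignment,
                 covered_population = covered_pop,
                 coverage_pct = covered_pop / scenario$total_population * 100,
                 facility_loads = loads,
                 capacity_status = setNames(capacity_status(loads, caps),
                                            open_set),
                 trajectory = data.frame(step = integer(),
                                         facility_id = character(),
                                         coverage_pct = numeric(),
                                         stringsAsFactors = FALSE),
                 total_population = scenario$total_population),
            class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf(paste0("<allocation_result> %d open facilities, %s of %s ",
                     "covered (%.1f%%), %d under / %d over capacity\n"),
              length(x$open_facilities),
              format(x$covered_population, big.mark = ","),
              format(x$total_population, big.mark = ","),
              x$coverage_pct,
              sum(x$capacity_status == "under"),
              sum(x$capacity_status == "over")))
  if (nrow(x$trajectory) > 0) {
    cat(sprintf("  added: %s\n",
                paste(sprintf("%s (%.1f%%)", x$trajectory$facility_id,
                              x$trajectory$coverage_pct), collapse = ", ")))
  }
  invisible(x)
}

#' Current-scenario coverage
#'
#' Opens every retained supply centre (post competing-centre merge), assigns
#' villages, and reports coverage, facility loads and capacity statuses.
#' Coverage counts villages by distance only (a village is covered when its
#' nearest open facility is within the cutoff); capacity enters as the
#' under/over classification of facility loads, not as a cap on coverage.
#'
#' @param scenario a `scenario`.
#' @return an `allocation_result`.
#' @export
solve_current <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  evaluate_open_set(scenario, retained_supply(scenario))
}

# covered population for an open set, distance-only counting (fast path
# shared by the greedy loop and the exhaustive oracle)
covered_pop_for <- function(scenario, open_set) {
  if (length(open_set) == 0) return(0)
  km <- scenario$distances$km[, open_set, drop = FALSE]
  d <- do.call(pmin, c(as.data.frame(km), na.rm = FALSE))
  sum(scenario$villages$population[is.finite(d) & d <= scenario$cutoff_km])
}

# demand-weighted total assignment distance (tie-break objective)
weighted_distance_for <- function(scenario, open_set) {
  a <- assign_villages(scenario, open_set)
  dem <- setNames(scenario$demand$bed_days_per_year,
                  scenario$demand$village_id)
  sum(dem[a$village_id[a$covered]] * a$distance_km[a$covered])
}

#' Incremental candidate addition (greedy maximal coverage)
#'
#' Starting from the current supply centres, repeatedly opens the candidate
#' centre that maximizes the marginal covered population; ties go first to
#' the candidate yielding the smaller demand-weighted total assignment
#' distance (the p-median flavour of the objective, strictly subordinate to
#' coverage), then to the smaller facility id.  The procedure stops when the
#' best achievable gain falls below `stop_threshold` percentage points of the
#' total population — the point at which adding new centres yields no further
#' meaningful improvement — or when `max_additions` is reached or candidates
#' run out.  The trajectory records coverage after every addition.
#'
#' @param scenario a `scenario`.
#' @return an `allocation_result` whose `trajectory` lists each added
#'   candidate and the coverage percentage after its addition.
#' @export
greedy_add_candidates <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  open_set <- retained_supply(scenario)
  candidates <- scenario$facilities$facility_id[
    scenario$facilities$role == "candidate"]
  total <- scenario$total_population
  covered <- covered_pop_for(scenario, open_set)
  traj <- list()
  step <- 0

  while (length(candidates) > 0 && step < scenario$max_additions) {
    gains <- vapply(candidates, function(cid) {
      covered_pop_for(scenario, c(open_set, cid)) - covered
    }, numeric(1))
    best_gain <- max(gains)
    if (best_gain / total * 100 < scenario$stop_threshold) break
    best <- candidates[gains == best_gain]
    if (length(best) > 1) {
      wd <- vapply(best, function(cid) {
        weighted_distance_for(scenario, c(open_set, cid))
      }, numeric(1))
      best <- best[wd == min(wd)]
    }
    chosen <- sort(best)[1]
    open_set <- c(open_set, chosen)
    candidates <- setdiff(candidates, chosen)
    covered <- covered + best_gain
    step <- step + 1
    traj[[step]] <- data.frame(step = step, facility_id = chosen,
                               coverage_pct = covered / total * 100,
                               stringsAsFactors = FALSE)
  }

  res <- evaluate_open_set(scenario, open_set)
  res$trajectory <- if (length(traj) > 0) do.call(rbind, traj)
                    else res$trajectory
  res
}

#' Best candidate subset by exhaustive enumeration
#'
#' Evaluates the covered population of the current supply centres plus every
#' candidate subset of size `k`, and returns a maximizer (ties resolved
#' lexicographically on the sorted subset).  This is an oracle for small
#' instances; the number of subsets is guarded at 1e5.
#'
#' @param scenario a `scenario`.
#' @param k subset size (0 <= k <= number of candidates).
#' @return list with `subset` (character vector of facility ids) and
#'   `covered_population`.
#' @export
exact_best_subset <- function(scenario, k) {
  stopifnot(inherits(scenario, "scenario"))
  check_count(k, "k")
  candidates <- sort(scenario$facilities$facility_id[
    scenario$facilities$role == "candidate"])
  if (k > length(candidates)) {
    stop(sprintf("k = %d exceeds the %d available candidates", k,
                 length(candidates)), call. = FALSE)
  }
  n_sub <- choose(length(candidates), k)
  if (n_sub > 1e5) {
    stop(sprintf(paste0("%.0f subsets exceed the enumeration guard (1e5); ",
                        "use a smaller instance"), n_sub), call. = FALSE)
  }
  base <- retained_supply(scenario)
  if (k == 0) {
    return(list(subset = character(0),
                covered_population = covered_pop_for(scenario, base)))
  }
  subsets <- utils::combn(candidates, k, simplify = FALSE)
  best <- NULL
  best_cov <- -Inf
  for (s in subsets) {  # combn order over sorted ids = lexicographic
    cov <- covered_pop_for(scenario, c(base, s))
    if (cov > best_cov) {
      best_cov <- cov
      best <- s
    }
  }
  list(subset = best, covered_population = best_cov)
}
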