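#' Plant a known coverage gap in a synthetic region
#'
#' Rewrites a region so that a geographically compact cluster of villages
#' holding at least `gap_fraction` of the population is beyond `cutoff_km`
#' (network distance) of every supply centre, while exactly one candidate
#' centre sits inside the gap and can cover all of it.  This emulates an
#' underserved area with a single obvious upgrade option, and gives a ground
#' truth for the allocation procedure: the planted candidate is the unique
#' improving move.
#'
#' The construction is deterministic given the region:
#' * the gap seed is the village in the northern belt (top 40% by northing)
#'   whose `cutoff_km` network neighbourhood holds the most population;
#'   villages accumulate around it by increasing network distance (never
#'   beyond `cutoff_km`, so a single centre at the seed covers the whole
#'   gap) until the requested population fraction is reached;
#' * supply centres whose catchment touches the gap are relocated to distinct
#'   covered villages far from the seed, and dropped if no relocation clears
#'   the gap;
#' * one candidate is moved to the seed village; all other candidates are
#'   co-located with retained supply centres so their marginal coverage gain
#'   is exactly zero, making the planted candidate the unique improving move.
#'
#' @param region a `region` with at least one candidate facility.
#' @param gap_fraction target uncovered population share, in (0, 1).
#' @param cutoff_km catchment cutoff used for the construction (default 20).
#' @return a modified copy of the region with attribute `planted_gap`: a list
#'   with `village_ids` (gap villages), `candidate_id` (the planted
#'   candidate), `achieved_fraction` (the uncovered population share actually
#'   planted, always >= `gap_fraction`), and `cutoff_km`.
#' @export
plant_coverage_gap <- function(region, gap_fraction, cutoff_km = 20) {
  stopifnot(inherits(region, "region"))
  if (!is.numeric(gap_fraction) || length(gap_fraction) != 1 ||
      gap_fraction <= 0 || gap_fraction >= 1) {
    stop("'gap_fraction' must be a single number in (0, 1)", call. = FALSE)
  }
  fac <- classify_facilities(region)
  cand_ids <- fac$facility_id[fac$role == "candidate"]
  if (length(cand_ids) == 0) {
    stop("cannot plant a coverage gap: region has no candidate facilities",
         call. = FALSE)
  }
  v <- region$villages
  total_pop <- sum(v$population)

  rg <- region_graph(region)
  # seed: northern-belt village with the most population within the cutoff
  north <- v$village_id[v$y_km >= stats::quantile(v$y_km, 0.6)]
  d_north <- shortest_distances(rg, north, v$village_id)$km
  pop_within <- apply(d_north, 1, function(r) {
    sum(v$population[r <= cutoff_km])
  })
  seed_id <- north[which.max(pop_within)]
  d_seed <- d_north[seed_id, ]

  ord <- order(d_seed)
  reach <- d_seed[ord] <= cutoff_km
  cum <- cumsum(v$population[ord]) / total_pop
  need <- which(cum >= gap_fraction)[1]
  if (is.na(need) || !all(reach[seq_len(need)])) {
    stop(sprintf(paste0("infeasible gap: only %.1f%% of the population lies ",
                        "within %.0f km of the gap seed village %s"),
                 100 * max(cum[reach], 0), cutoff_km, seed_id),
         call. = FALSE)
  }
  gap_ids <- v$village_id[ord[seq_len(need)]]
  achieved <- cum[need]
  non_gap <- setdiff(v$village_id, gap_ids)
  if (length(non_gap) == 0) {
    stop("infeasible gap: every village would be inside the gap",
         call. = FALSE)
  }

  out <- region
  supply_ids <- fac$facility_id[fac$role == "supply"]
  # relocation targets: non-gap villages, farthest from the seed first
  tgt <- non_gap[order(d_seed[non_gap], decreasing = TRUE)]

  if (length(supply_ids) > 0) {
    d_sup <- shortest_distances(rg, supply_ids, gap_ids)$km
    offenders <- supply_ids[apply(d_sup, 1, function(r) any(r <= cutoff_km))]
    ti <- 1
    for (fid in offenders) {
      host <- v[v$village_id == tgt[min(ti, length(tgt))], ]
      ti <- ti + 1
      out$facilities[out$facilities$facility_id == fid,
                     c("x_km", "y_km")] <- host[, c("x_km", "y_km")]
    }
    # verify relocation cleared the gap; drop any centre that still reaches it
    rg2 <- region_graph(out)
    d_sup2 <- shortest_distances(rg2, supply_ids, gap_ids)$km
    still <- supply_ids[apply(d_sup2, 1, function(r) any(r <= cutoff_km))]
    if (length(still) > 0) {
      out$facilities <- out$facilities[
        !out$facilities$facility_id %in% still, , drop = FALSE]
      supply_ids <- setdiff(supply_ids, still)
    }
  }

  # plant one candidate at the gap seed village
  planted <- cand_ids[1]
  seed_xy <- v[v$village_id == seed_id, c("x_km", "y_km")]
  out$facilities[out$facilities$facility_id == planted,
                 c("x_km", "y_km")] <- seed_xy

  # neutralize the remaining candidates: co-locate each with a retained
  # supply centre (identical catchment, zero marginal gain)
  others <- setdiff(cand_ids, planted)
  if (length(others) > 0 && length(supply_ids) > 0) {
    anchors <- out$facilities[out$facilities$facility_id %in% supply_ids, ]
    for (i in seq_along(others)) {
      a <- anchors[((i - 1) %% nrow(anchors)) + 1, ]
      out$facilities[out$facilities$facility_id == others[i],
                     c("x_km", "y_km")] <- a[, c("x_km", "y_km")]
    }
  }

  attr(out, "planted_gap") <- list(village_ids = gap_ids,
                                   candidate_id = planted,
                                   achieved_fraction = achieved,
                                   cutoff_km = cutoff_km)
  out
}
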