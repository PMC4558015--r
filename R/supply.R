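#' Annual obstetric bed-day supply of a facility
#'
#' Supply is the obstetric bed strength multiplied by 365 days.
#'
#' @param obstetric_beds number of obstetric beds (non-negative integer).
#' @return bed-days available per year.
#' @export
bed_days_supply <- function(obstetric_beds) {
  check_count(obstetric_beds, "obstetric_beds")
  obstetric_beds * 365
}

#' Classify facilities into supply, candidate, or excluded roles
#'
#' A *supply centre* currently provides free C-section services: a public
#' facility performing C-sections, or a private facility enrolled in the
#' free-care programme (CY) and performing C-sections.  A *candidate centre*
#' could be operationalized: a private non-enrolled facility that performs
#' C-sections (could be contracted), or a public facility offering basic
#' obstetric care but lacking C-section capability (could be upgraded).
#' Everything else (private, no C-section capability) is *excluded*.
#'
#' @param sector character vector, `"public"` or `"private"`.
#' @param performs_csection logical vector.
#' @param cy_enrolled logical vector (free-care programme enrolment; only
#'   meaningful for private facilities).
#' @return character vector of roles: `"supply"`, `"candidate"`, `"excluded"`.
#' @export
classify_facility <- function(sector, performs_csection, cy_enrolled) {
  if (anyNA(sector) || !all(sector %in% c("public", "private"))) {
    stop("'sector' must be \"public\" or \"private\" with no missing values",
         call. = FALSE)
  }
  if (anyNA(performs_csection) || !is.logical(performs_csection)) {
    stop("'performs_csection' must be logical with no missing values",
         call. = FALSE)
  }
  if (anyNA(cy_enrolled) || !is.logical(cy_enrolled)) {
    stop("'cy_enrolled' must be logical with no missing values",
         call. = FALSE)
  }
  supply <- (sector == "public" & performs_csection) |
    (sector == "private" & performs_csection & cy_enrolled)
  candidate <- (sector == "private" & performs_csection & !cy_enrolled) |
    (sector == "public" & !performs_csection)
  ifelse(supply, "supply", ifelse(candidate, "candidate", "excluded"))
}

#' Classify a region's facility table
#'
#' Adds `role` and `bed_days_per_year` columns to the facility table.
#'
#' @param region a `region` object.
#' @return the facility data frame with `role` and `bed_days_per_year` added.
#' @export
classify_facilities <- function(region) {
  stopifnot(inherits(region, "region"))
  f <- region$facilities
  f$role <- classify_facility(f$sector, f$performs_csection, f$cy_enrolled)
  f$bed_days_per_year <- bed_days_supply(f$obstetric_beds)
  f
}

#' Merge competing supply centres
#'
#' Supply centres located close to each other compete for the same catchment;
#' within each group of centres pairwise closer than `epsilon_km` (network
#' distance, single-linkage closure of the pairwise relation) only the centre
#' with the greatest annual bed-day capacity is retained, ties broken by
#' lexicographically smallest facility id.  With `epsilon_km = 0` the merge is
#' the identity.
#'
#' @param supply a data frame of supply centres with columns `facility_id`
#'   and `bed_days_per_year`.
#' @param fac_dist square matrix of pairwise network distances (km) between
#'   the supply centres, dimnames = facility ids.
#' @param epsilon_km merge radius in km (default 1: roughly "same town").
#' @return a list with `retained` (the surviving rows), `merged_into`
#'   (named character vector mapping every input facility id to the id that
#'   absorbed it, `""` if retained).
#' @export
merge_competing_centers <- function(supply, fac_dist, epsilon_km = 1) {
  check_nonneg(epsilon_km, "epsilon_km")
  n <- nrow(supply)
  merged_into <- setNames(rep("", n), supply$facility_id)
  if (n == 0) {
    return(list(retained = supply, merged_into = merged_into))
  }
  d <- fac_dist[supply$facility_id, supply$facility_id, drop = FALSE]
  adj <- is.finite(d) & d < epsilon_km
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep <- logical(n)
  for (grp in split(seq_len(n), comp)) {
    cap <- supply$bed_days_per_year[grp]
    best <- grp[cap == max(cap)]
    winner <- best[order(supply$facility_id[best])][1]
    keep[winner] <- TRUE
    losers <- setdiff(grp, winner)
    merged_into[losers] <- supply$facility_id[winner]
  }
  list(retained = supply[keep, , drop = FALSE], merged_into = merged_into)
}
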