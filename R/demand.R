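#' Expected annual births in a village
#'
#' Births per year are the block-level crude birth rate (CBR, births per 1000
#' population per year) applied to the village population:
#' `births = cbr / 1000 * population`.  No rounding is applied: demand is an
#' expectation, and rounding would break linearity.
#'
#' @param population village population (persons, >= 0).
#' @param cbr crude birth rate (births per 1000 persons per year, >= 0).
#' @return expected births per year (numeric, vectorized).
#' @export
annual_births <- function(population, cbr) {
  check_nonneg(population, "population")
  check_nonneg(cbr, "cbr")
  cbr / 1000 * population
}

#' Expected daily births from annual births
#'
#' @param births_per_year expected births per year (>= 0).
#' @return births per day, `births_per_year / 365`.
#' @export
daily_births <- function(births_per_year) {
  check_nonneg(births_per_year, "births_per_year")
  births_per_year / 365
}

#' Obstetric bed-day demand from daily births
#'
#' A fixed share of births is assumed complicated (WHO assumption, 15%) and
#' occupies an obstetric bed for `complicated_stay_days` (default 5 days,
#' covering caesarean recovery); the remainder stay `normal_stay_days`
#' (default 2 days, the Indian federal norm for normal deliveries).  With the
#' defaults the demand is `births_per_day * (0.85*2 + 0.15*5) =
#' births_per_day * 2.45` bed-days per day.
#'
#' @param births_per_day expected births per day (>= 0).
#' @param complicated_share proportion of births that are complicated.
#' @param normal_stay_days bed-days per normal delivery.
#' @param complicated_stay_days bed-days per complicated delivery.
#' @return obstetric bed-days required per day.
#' @export
bed_days_demand <- function(births_per_day, complicated_share = 0.15,
                            normal_stay_days = 2, complicated_stay_days = 5) {
  check_nonneg(births_per_day, "births_per_day")
  check_nonneg(complicated_share, "complicated_share")
  if (any(complicated_share > 1)) {
    stop("'complicated_share' must be <= 1", call. = FALSE)
  }
  check_nonneg(normal_stay_days, "normal_stay_days")
  check_nonneg(complicated_stay_days, "complicated_stay_days")
  births_per_day * ((1 - complicated_share) * normal_stay_days +
                      complicated_share * complicated_stay_days)
}

#' Per-village obstetric demand table
#'
#' Joins each village to its block CBR and evaluates the demand chain:
#' annual births, daily births, bed-days per day, and the annualized
#' bed-days per year (`bed_days_per_day * 365`) used for all capacity
#' comparisons, so that demand and supply are in the same units
#' (bed-days per year).
#'
#' @param region a `region` object (see [generate_region()]).
#' @param complicated_share,normal_stay_days,complicated_stay_days
#'   passed to [bed_days_demand()].
#' @return a data frame with one row per village: `village_id`, `population`,
#'   `cbr`, `births_per_year`, `births_per_day`, `bed_days_per_day`,
#'   `bed_days_per_year`.
#' @export
village_demand_table <- function(region, complicated_share = 0.15,
                                 normal_stay_days = 2,
                                 complicated_stay_days = 5) {
  stopifnot(inherits(region, "region"))
  v <- region$villages
  if (nrow(v) == 0) {
    return(data.frame(village_id = character(), population = numeric(),
                      cbr = numeric(), births_per_year = numeric(),
                      births_per_day = numeric(), bed_days_per_day = numeric(),
                      bed_days_per_year = numeric(),
                      stringsAsFactors = FALSE))
  }
  idx <- match(v$block_id, region$blocks$block_id)
  if (anyNA(idx) || anyNA(region$blocks$cbr_per_1000[idx])) {
    bad <- v$village_id[is.na(idx) | is.na(region$blocks$cbr_per_1000[idx])]
    stop(sprintf("missing block CBR for village(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  cbr <- region$blocks$cbr_per_1000[idx]
  x <- annual_births(v$population, cbr)
  y <- daily_births(x)
  bdd <- bed_days_demand(y, complicated_share, normal_stay_days,
                         complicated_stay_days)
  data.frame(village_id = v$village_id, population = v$population, cbr = cbr,
             births_per_year = x, births_per_day = y, bed_days_per_day = bdd,
             bed_days_per_year = bdd * 365, stringsAsFactors = FALSE)
}

#' Demand normalized per 1000 population
#'
#' Optional reporting normalization (bed-days per year per 1000 persons);
#' never used in capacity comparisons, which compare totals.
#'
#' @param demand_table output of [village_demand_table()].
#' @return the table with an extra `bed_days_per_year_per_1000` column.
#' @export
demand_per_1000 <- function(demand_table) {
  demand_table$bed_days_per_year_per_1000 <-
    ifelse(demand_table$population > 0,
           demand_table$bed_days_per_year / demand_table$population * 1000, 0)
  demand_table
}
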