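# two supply centres and two candidates on a line; distances are |dx|
two_centre_region <- function() {
  line_region(village_x = c(5, 8, 25, 60),
              village_pop = c(100, 200, 300, 400),
              facility_x = c(0, 30, 58, 90),
              facility_attrs = data.frame(
                sector = c("public", "public", "private", "private"),
                performs_csection = c(TRUE, TRUE, TRUE, TRUE),
                cy_enrolled = c(FALSE, FALSE, FALSE, FALSE),
                obstetric_beds = c(10, 4, 6, 6)))
}

test_that("villages go to the nearest open facility within the cutoff", {
  sc <- build_scenario(two_centre_region(), cutoff_km = 20)
  a <- assign_villages(sc, c("F01", "F02"))
  expect_equal(a$facility_id[a$village_id == "V01"], "F01")  # 5 vs 25
  expect_equal(a$facility_id[a$village_id == "V02"], "F01")  # 8 vs 22
  expect_equal(a$facility_id[a$village_id == "V03"], "F02")  # 25 vs 5
  expect_true(is.na(a$facility_id[a$village_id == "V04"]))   # 30 km away
  expect_false(a$covered[a$village_id == "V04"])
})

test_that("assignment ties break on capacity then id", {
  # village equidistant (10 km) from A (10 beds) and B (4 beds)
  r <- line_region(village_x = 10, village_pop = 100,
                   facility_x = c(0, 20),
                   facility_attrs = data.frame(
                     sector = "public", performs_csection = TRUE,
                     cy_enrolled = FALSE, obstetric_beds = c(10, 4)))
  sc <- build_scenario(r, cutoff_km = 20, merge = FALSE)
  a <- assign_villages(sc, c("F01", "F02"))
  expect_equal(a$facility_id, "F01")
  # equal capacity: smaller id wins
  r2 <- line_region(10, 100, c(0, 20),
                    data.frame(sector = "public", performs_csection = TRUE,
                               cy_enrolled = FALSE, obstetric_beds = c(4, 4)))
  sc2 <- build_scenario(r2, cutoff_km = 20, merge = FALSE)
  expect_equal(assign_villages(sc2, c("F01", "F02"))$facility_id, "F01")
})

test_that("facility loads sum assigned village demand and conserve totals", {
  sc <- build_scenario(two_centre_region(), cutoff_km = 20)
  a <- assign_villages(sc, c("F01", "F02"))
  loads <- facility_load(a, sc$demand)
  dem <- setNames(sc$demand$bed_days_per_year, sc$demand$village_id)
  expect_equal(unname(loads["F01"]), unname(dem["V01"] + dem["V02"]))
  expect_equal(unname(loads["F02"]), unname(dem["V03"]))
  expect_equal(sum(loads), sum(dem[a$village_id[a$covered]]))
  # two villages of 612.5 bed-days each
  r <- line_region(c(2, 4), c(10000, 10000), 0, fac_attrs(1, 0))
  scr <- build_scenario(r, cutoff_km = 20)
  ar <- assign_villages(scr, "F01")
  expect_equal(unname(facility_load(ar, scr$demand)["F01"]), 1225)
})

test_that("capacity classification puts equality in 'over'", {
  expect_equal(capacity_status(800, 730), "under")
  expect_equal(capacity_status(730, 730), "over")
  expect_equal(capacity_status(0, 730), "over")
  expect_error(capacity_status(-1, 10), "load")
  expect_error(capacity_status(1, -10), "supply")
})

test_that("solve_current covers boundary scenarios", {
  # no supply centres at all -> 0% coverage
  r0 <- line_region(c(5, 9), c(100, 100), 30,
                    data.frame(sector = "private", performs_csection = TRUE,
                               cy_enrolled = FALSE, obstetric_beds = 5))
  res0 <- solve_current(build_scenario(r0, cutoff_km = 20))
  expect_equal(res0$coverage_pct, 0)
  expect_equal(res0$covered_population, 0)
  # one centre in reach of everything -> 100%
  r1 <- line_region(c(5, 9), c(100, 100), 7, fac_attrs(1, 0))
  res1 <- solve_current(build_scenario(r1, cutoff_km = 20))
  expect_equal(res1$coverage_pct, 100)
})

test_that("the competing-centre merge changes the open set, not the maths", {
  # two supply centres 0.5 km apart: merged run opens only the big one
  r <- line_region(village_x = c(5, 9), village_pop = c(100, 100),
                   facility_x = c(0, 0.5),
                   facility_attrs = data.frame(
                     sector = "public", performs_csection = TRUE,
                     cy_enrolled = FALSE, obstetric_beds = c(4, 10)))
  merged <- solve_current(build_scenario(r, cutoff_km = 20, merge = TRUE))
  plain <- solve_current(build_scenario(r, cutoff_km = 20, merge = FALSE))
  expect_equal(merged$open_facilities, "F02")
  expect_setequal(plain$open_facilities, c("F01", "F02"))
  expect_equal(merged$coverage_pct, plain$coverage_pct)
})

test_that("greedy opens the single improving candidate and then stops", {
  # supply covers V01-V02; candidate F02 covers the far V03; F03 nothing new
  r <- line_region(village_x = c(5, 9, 50),
                   village_pop = c(100, 100, 500),
                   facility_x = c(0, 52, 7),
                   facility_attrs = data.frame(
                     sector = c("public", "private", "private"),
                     performs_csection = TRUE, cy_enrolled = FALSE,
                     obstetric_beds = 5))
  sc <- build_scenario(r, cutoff_km = 20)
  res <- greedy_add_candidates(sc)
  expect_equal(res$trajectory$facility_id, "F02")
  expect_equal(res$coverage_pct, 100)
})

test_that("a prohibitive stop threshold reproduces the current scenario", {
  sc <- build_scenario(two_centre_region(), cutoff_km = 20,
                       stop_threshold = 101)
  res <- greedy_add_candidates(sc)
  cur <- solve_current(sc)
  expect_equal(nrow(res$trajectory), 0)
  expect_equal(res$coverage_pct, cur$coverage_pct)
  expect_setequal(res$open_facilities, cur$open_facilities)
})

test_that("coverage is monotone along the greedy trajectory", {
  for (s in 1:10) {
    sc <- build_scenario(generate_region(small_spec(s)), cutoff_km = 12,
                         stop_threshold = 0.5)
    res <- greedy_add_candidates(sc)
    if (nrow(res$trajectory) > 1) {
      expect_true(all(diff(res$trajectory$coverage_pct) >= -1e-12))
    }
    expect_gte(res$coverage_pct,
               solve_current(sc)$coverage_pct - 1e-12)
  }
})

test_that("greedy never beats the exhaustive optimum, and matches it when one candidate dominates", {
  set.seed(202)
  for (s in 1:50) {
    sc <- build_scenario(generate_region(small_spec(s, n_candidates = 4)),
                         cutoff_km = sample(c(8, 10, 12), 1),
                         stop_threshold = 0.5)
    res <- greedy_add_candidates(sc)
    k <- nrow(res$trajectory)
    best <- exact_best_subset(sc, k)
    expect_lte(res$covered_population, best$covered_population)
    # and every greedy prefix respects its own optimum
    if (k >= 1) {
      b1 <- exact_best_subset(sc, 1)
      first <- res$trajectory$coverage_pct[1] / 100 * sc$total_population
      expect_lte(first, b1$covered_population + 1e-9)
    }
  }
  # dominant candidate: F02 covers the big far village, F03 duplicates supply
  r <- line_region(village_x = c(5, 50), village_pop = c(100, 900),
                   facility_x = c(0, 52, 3),
                   facility_attrs = data.frame(
                     sector = c("public", "private", "private"),
                     performs_csection = TRUE, cy_enrolled = FALSE,
                     obstetric_beds = 5))
  sc <- build_scenario(r, cutoff_km = 20)
  res <- greedy_add_candidates(sc)
  expect_equal(res$covered_population,
               exact_best_subset(sc, nrow(res$trajectory))$covered_population)
})

test_that("exact_best_subset handles its boundary cases and the guard", {
  sc <- build_scenario(two_centre_region(), cutoff_km = 20)
  cur <- solve_current(sc)
  expect_equal(exact_best_subset(sc, 0)$covered_population,
               cur$covered_population)
  ncand <- sum(sc$facilities$role == "candidate")
  full <- exact_best_subset(sc, ncand)
  all_open <- assign_villages(
    sc, sc$facilities$facility_id[sc$facilities$merged_into == ""])
  pop <- setNames(sc$villages$population, sc$villages$village_id)
  expect_equal(full$covered_population, sum(pop[all_open$covered]))
  expect_error(exact_best_subset(sc, ncand + 5), "exceeds")
})

test_that("an 8-village 4-candidate instance matches direct subset evaluation", {
  r <- line_region(village_x = c(2, 6, 22, 26, 44, 48, 66, 70),
                   village_pop = c(50, 60, 70, 80, 90, 100, 110, 120),
                   facility_x = c(4, 24, 46, 68, 90),
                   facility_attrs = data.frame(
                     sector = c("public", rep("private", 4)),
                     performs_csection = TRUE, cy_enrolled = FALSE,
                     obstetric_beds = 5))
  sc <- build_scenario(r, cutoff_km = 5)
  # direct evaluation of all 6 pairs of the 4 candidates
  cands <- sort(sc$facilities$facility_id[sc$facilities$role == "candidate"])
  pop <- setNames(sc$villages$population, sc$villages$village_id)
  direct <- -Inf
  for (pair in utils::combn(cands, 2, simplify = FALSE)) {
    a <- assign_villages(sc, c("F01", pair))
    direct <- max(direct, sum(pop[a$covered]))
  }
  expect_equal(exact_best_subset(sc, 2)$covered_population, direct)
})

test_that("capacitated assignment spills demand but never assigns out of range", {
  # two villages, near facility too small for both, far facility roomy
  r <- line_region(village_x = c(1, 2), village_pop = c(10000, 10000),
                   facility_x = c(0, 15),
                   facility_attrs = data.frame(
                     sector = "public", performs_csection = TRUE,
                     cy_enrolled = FALSE, obstetric_beds = c(2, 30)))
  sc <- build_scenario(r, cutoff_km = 20, capacitated = TRUE,
                       merge = FALSE)
  a <- assign_villages(sc, c("F01", "F02"))
  expect_true(all(a$covered))
  # one village spilled to the roomy far facility
  expect_setequal(a$facility_id, c("F01", "F02"))
  expect_true(all(a$distance_km <= 20))
  # both fit nowhere beyond cutoff: stays uncovered
  r2 <- line_region(50, 100, 0, fac_attrs(1, 0))
  sc2 <- build_scenario(r2, cutoff_km = 20, capacitated = TRUE)
  expect_false(assign_villages(sc2, "F01")$covered)
})

test_that("opening a facility never increases a village's assignment distance", {
  for (s in 1:5) {
    sc <- build_scenario(generate_region(small_spec(s)), cutoff_km = 12)
    sup <- solve_current(sc)
    cand <- sc$facilities$facility_id[sc$facilities$role == "candidate"][1]
    wider <- assign_villages(sc, c(sup$open_facilities, cand))
    base <- sup$assignment
    both <- base$covered & wider$covered
    expect_true(all(wider$distance_km[both] <= base$distance_km[both] + 1e-9))
    expect_true(all(wider$covered >= base$covered))
  }
})
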