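test_that("shared endpoints fuse into single nodes", {
  roads <- data.frame(road_id = c("R1", "R2"),
                      x1 = c(0, 3), y1 = c(0, 0),
                      x2 = c(3, 7), y2 = c(0, 0),
                      length_km = c(3, 4), stringsAsFactors = FALSE)
  rg <- build_graph(roads, data.frame(village_id = character(),
                                      x_km = numeric(), y_km = numeric()),
                    data.frame(facility_id = character(),
                               x_km = numeric(), y_km = numeric()))
  expect_equal(nrow(rg$nodes), 3)
  expect_equal(igraph::ecount(rg$graph), 2)
})

test_that("entities attach with Euclidean connectors and path distances add up", {
  roads <- data.frame(road_id = c("R1", "R2"),
                      x1 = c(0, 3), y1 = c(0, 0),
                      x2 = c(3, 7), y2 = c(0, 0),
                      length_km = c(3, 4), stringsAsFactors = FALSE)
  v <- data.frame(village_id = "V1", x_km = 0, y_km = 0.1)
  f <- data.frame(facility_id = "F1", x_km = 7, y_km = 0)
  rg <- build_graph(roads, v, f)
  expect_equal(rg$attachments$connector_km[rg$attachments$id == "V1"], 0.1)
  expect_false(rg$attachments$long_connector[rg$attachments$id == "V1"])
  dm <- shortest_distances(rg, "V1", "F1")
  expect_equal(dm$km["V1", "F1"], 7.1)  # 0.1 connector + 3 + 4
})

test_that("triangle shortcut beats the long edge", {
  roads <- data.frame(road_id = c("R1", "R2", "R3"),
                      x1 = c(0, 3, 0), y1 = c(0, 0, 0),
                      x2 = c(3, 3, 3), y2 = c(0, 4, 4),
                      length_km = c(3, 4, 10), stringsAsFactors = FALSE)
  v <- data.frame(village_id = "A", x_km = 0, y_km = 0)
  f <- data.frame(facility_id = "C", x_km = 3, y_km = 4)
  rg <- build_graph(roads, v, f)
  expect_equal(shortest_distances(rg, "A", "C")$km["A", "C"], 7)
})

test_that("empty road layers and unknown ids raise errors", {
  expect_error(build_graph(data.frame(), data.frame(), data.frame()),
               "empty")
  roads <- data.frame(road_id = "R1", x1 = 0, y1 = 0, x2 = 1, y2 = 0,
                      length_km = 1)
  rg <- build_graph(roads,
                    data.frame(village_id = "V1", x_km = 0, y_km = 0),
                    data.frame(facility_id = "F1", x_km = 1, y_km = 0))
  expect_error(shortest_distances(rg, "V1", "F9"), "F9")
  expect_error(catchment("F9", shortest_distances(rg, "V1", "F1", 20)), "F9")
})

test_that("network distances match brute-force simple-path enumeration", {
  set.seed(4711)
  for (rep in seq_len(100)) {
    n <- sample(5:12, 1)
    g <- random_road_graph(n)
    vi <- sample(n, 3)
    fi <- sample(n, 3)
    v <- data.frame(village_id = sprintf("V%d", vi),
                    x_km = g$x[vi], y_km = g$y[vi])
    f <- data.frame(facility_id = sprintf("F%d", fi),
                    x_km = g$x[fi], y_km = g$y[fi])
    rg <- build_graph(g$roads, v, f)
    dm <- shortest_distances(rg, v$village_id, f$facility_id)
    for (a in seq_len(3)) {
      for (b in seq_len(3)) {
        expect_equal(dm$km[a, b],
                     brute_shortest(g$edges, n, vi[a], fi[b]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("adding an edge never increases any distance", {
  set.seed(99)
  for (rep in seq_len(20)) {
    n <- sample(6:10, 1)
    g <- random_road_graph(n, extra = 2)
    vi <- 1:2; fi <- (n - 1):n
    v <- data.frame(village_id = sprintf("V%d", vi), x_km = g$x[vi],
                    y_km = g$y[vi])
    f <- data.frame(facility_id = sprintf("F%d", fi), x_km = g$x[fi],
                    y_km = g$y[fi])
    d1 <- shortest_distances(build_graph(g$roads, v, f),
                             v$village_id, f$facility_id)$km
    # add one more edge between two random distinct nodes
    ab <- sample(n, 2)
    w <- sqrt((g$x[ab[1]] - g$x[ab[2]])^2 + (g$y[ab[1]] - g$y[ab[2]])^2)
    if (w == 0) next
    roads2 <- rbind(g$roads,
                    data.frame(road_id = "RX", x1 = g$x[ab[1]],
                               y1 = g$y[ab[1]], x2 = g$x[ab[2]],
                               y2 = g$y[ab[2]], length_km = w))
    d2 <- shortest_distances(build_graph(roads2, v, f),
                             v$village_id, f$facility_id)$km
    expect_true(all(d2 <= d1 + 1e-9))
  }
})

test_that("catchment boundary is inclusive and monotone in the cutoff", {
  r <- line_region(village_x = c(5, 20, 20.001, 35),
                   village_pop = rep(100, 4),
                   facility_x = 0, facility_attrs = fac_attrs(1, 0))
  rg <- region_graph(r)
  dm <- shortest_distances(rg, r$villages$village_id, "F01", cutoff_km = 20)
  got <- catchment("F01", dm)
  expect_true(all(c("V01", "V02") %in% got))   # 20.0 km included
  expect_false("V03" %in% got)                 # 20.001 km excluded
  dm_all <- shortest_distances(rg, r$villages$village_id, "F01")
  c10 <- catchment("F01", dm_all, cutoff_km = 10)
  c20 <- catchment("F01", dm_all, cutoff_km = 20)
  expect_true(all(c10 %in% c20))
  # facility with no village in range
  dm_far <- shortest_distances(rg, r$villages$village_id, "F01",
                               cutoff_km = 1)
  expect_length(catchment("F01", dm_far), 0)
})

test_that("entries beyond the cutoff are stored as +Inf", {
  r <- line_region(c(5, 30), c(10, 10), 0, fac_attrs(1, 0))
  dm <- shortest_distances(region_graph(r), r$villages$village_id, "F01",
                           cutoff_km = 20)
  expect_equal(dm$km["V01", "F01"], 5)
  expect_true(is.infinite(dm$km["V02", "F01"]))
})
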