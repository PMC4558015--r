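#' Specification of a synthetic region
#'
#' Parameter bundle for [generate_region()].  The defaults emulate one Indian
#' district as described for the study setting: about 2 million people split
#' into 10-20 blocks (sub-districts) of 90-100 villages each, block crude
#' birth rates in a plausible 15-30 per 1000 range, facilities with 0-30
#' obstetric beds, and a connected road network in a square planar frame of
#' roughly district extent.
#'
#' @param n_blocks number of blocks.
#' @param villages_per_block integer (low, high) range of villages per block.
#' @param total_population total persons across all villages.
#' @param cbr_range (low, high) crude birth rate range (births/1000/year).
#' @param n_supply_centers number of current free C-section supply centres.
#' @param n_candidates number of candidate centres.
#' @param bed_range integer (low, high) obstetric bed count range.
#' @param extent_km side length of the square region (km).
#' @param road_style `"random-planar"` (minimum-spanning-tree backbone over
#'   settlements plus nearest-neighbour shortcuts) or `"grid"` (regular road
#'   grid).
#' @param seed integer RNG seed; a fixed seed reproduces the region exactly.
#' @param sigma_log dispersion (sdlog) of the heavy-tailed (log-normal)
#'   village population distribution before rescaling.
#' @param snap_tolerance_km village/facility road-snap tolerance in km.
#' @return a `region_spec` object (validated list).
#' @export
region_spec <- function(n_blocks = 12,
                        villages_per_block = c(90, 100),
                        total_population = 2e6,
                        cbr_range = c(15, 30),
                        n_supply_centers = 18,
                        n_candidates = 10,
                        bed_range = c(0, 30),
                        extent_km = 80,
                        road_style = c("random-planar", "grid"),
                        seed = 1L,
                        sigma_log = 0.8,
                        snap_tolerance_km = 2) {
  check_count(n_blocks, "n_blocks")
  if (n_blocks < 1) stop("'n_blocks' must be >= 1", call. = FALSE)
  check_range(villages_per_block, "villages_per_block")
  check_count(villages_per_block, "villages_per_block")
  if (villages_per_block[1] < 1) {
    stop("'villages_per_block' low must be >= 1", call. = FALSE)
  }
  check_nonneg(total_population, "total_population")
  if (total_population <= 0) {
    stop("'total_population' must be > 0", call. = FALSE)
  }
  check_range(cbr_range, "cbr_range")
  check_nonneg(cbr_range, "cbr_range")
  check_count(n_supply_centers, "n_supply_centers")
  check_count(n_candidates, "n_candidates")
  check_range(bed_range, "bed_range")
  check_count(bed_range, "bed_range")
  check_nonneg(extent_km, "extent_km")
  if (extent_km <= 0) stop("'extent_km' must be > 0", call. = FALSE)
  road_style <- match.arg(road_style)
  if (length(seed) != 1 || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  check_nonneg(sigma_log, "sigma_log")
  check_nonneg(snap_tolerance_km, "snap_tolerance_km")
  structure(list(n_blocks = as.integer(n_blocks),
                 villages_per_block = as.integer(villages_per_block),
                 total_population = total_population,
                 cbr_range = cbr_range,
                 n_supply_centers = as.integer(n_supply_centers),
                 n_candidates = as.integer(n_candidates),
                 bed_range = as.integer(bed_range),
                 extent_km = extent_km,
                 road_style = road_style,
                 seed = as.integer(seed),
                 sigma_log = sigma_log,
                 snap_tolerance_km = snap_tolerance_km),
            class = "region_spec")
}

# sample() without the scalar-x surprise
resample <- function(x, ...) x[sample.int(length(x), ...)]

# largest-remainder rounding: integer vector summing exactly to total
round_to_total <- function(w, total) {
  p <- w / sum(w) * total
  f <- floor(p)
  r <- total - sum(f)
  if (r > 0) {
    top <- order(p - f, decreasing = TRUE)[seq_len(r)]
    f[top] <- f[top] + 1
  }
  f
}

#' Generate a synthetic region
#'
#' Deterministically (for a fixed seed) generates villages clustered around
#' block centres, heavy-tailed village populations rescaled to the requested
#' total, one crude birth rate per block, a connected road network, and
#' facilities placed at villages with attributes consistent with their
#' intended role (supply centres: public performing C-sections or
#' programme-enrolled private; candidates: non-enrolled private performing
#' C-sections or public without C-section capability).
#'
#' @param spec a `region_spec`.
#' @return a `region` object: data frames `villages` (village_id, name,
#'   block_id, x_km, y_km, population), `blocks` (block_id, cbr_per_1000),
#'   `facilities` (facility_id, x_km, y_km, sector, performs_csection,
#'   cy_enrolled, obstetric_beds), `roads` (road segments), plus `extent_km`,
#'   `snap_tolerance_km` and `seed`.
#' @export
generate_region <- function(spec) {
  if (!inherits(spec, "region_spec")) {
    stop("'spec' must be a region_spec object", call. = FALSE)
  }
  with_seed(spec$seed, {
    ext <- spec$extent_km
    # block centres on a jittered grid
    m <- ceiling(sqrt(spec$n_blocks))
    cells <- utils::head(expand.grid(i = seq_len(m), j = seq_len(m)),
                         spec$n_blocks)
    step <- ext / m
    bx <- (cells$i - 0.5) * step + stats::runif(spec$n_blocks, -0.15, 0.15) * step
    by <- (cells$j - 0.5) * step + stats::runif(spec$n_blocks, -0.15, 0.15) * step

    nv_per_block <- resample(seq(spec$villages_per_block[1],
                                 spec$villages_per_block[2]),
                             spec$n_blocks, replace = TRUE)
    n_villages <- sum(nv_per_block)
    block_of <- rep(seq_len(spec$n_blocks), nv_per_block)
    sd_v <- step / 2.5
    vx <- pmin(pmax(stats::rnorm(n_villages, bx[block_of], sd_v), 0), ext)
    vy <- pmin(pmax(stats::rnorm(n_villages, by[block_of], sd_v), 0), ext)

    w <- stats::rlnorm(n_villages, meanlog = 0, sdlog = spec$sigma_log)
    pop <- round_to_total(w, spec$total_population)

    villages <- data.frame(
      village_id = sprintf("V%04d", seq_len(n_villages)),
      name = sprintf("village-%04d", seq_len(n_villages)),
      block_id = sprintf("B%02d", block_of),
      x_km = vx, y_km = vy, population = pop,
      stringsAsFactors = FALSE)

    blocks <- data.frame(
      block_id = sprintf("B%02d", seq_len(spec$n_blocks)),
      cbr_per_1000 = stats::runif(spec$n_blocks, spec$cbr_range[1],
                                  spec$cbr_range[2]),
      stringsAsFactors = FALSE)

    # facilities at (near) villages, supply hosts weighted by population
    n_fac <- spec$n_supply_centers + spec$n_candidates
    if (n_fac > n_villages) {
      stop("more facilities requested than villages to host them",
           call. = FALSE)
    }
    hosts <- sample(n_villages, n_fac, prob = pop + 1)
    role_intent <- rep(c("supply", "candidate"),
                       c(spec$n_supply_centers, spec$n_candidates))
    sector <- character(n_fac)
    performs <- logical(n_fac)
    cy <- logical(n_fac)
    for (i in seq_len(n_fac)) {
      if (role_intent[i] == "supply") {
        sector[i] <- sample(c("public", "private"), 1)
        performs[i] <- TRUE
        cy[i] <- sector[i] == "private"
      } else {
        if (stats::runif(1) < 0.5) {
          sector[i] <- "private"; performs[i] <- TRUE; cy[i] <- FALSE
        } else {
          sector[i] <- "public"; performs[i] <- FALSE; cy[i] <- FALSE
        }
      }
    }
    beds <- resample(seq(spec$bed_range[1], spec$bed_range[2]), n_fac,
                     replace = TRUE)
    facilities <- data.frame(
      facility_id = sprintf("F%03d", seq_len(n_fac)),
      x_km = vx[hosts] + stats::runif(n_fac, -0.3, 0.3),
      y_km = vy[hosts] + stats::runif(n_fac, -0.3, 0.3),
      sector = sector, performs_csection = performs, cy_enrolled = cy,
      obstetric_beds = beds,
      stringsAsFactors = FALSE)

    roads <- switch(spec$road_style,
      "random-planar" = roads_random_planar(villages, facilities),
      "grid" = roads_grid(ext))

    structure(list(villages = villages, blocks = blocks,
                   facilities = facilities, roads = roads,
                   extent_km = ext,
                   snap_tolerance_km = spec$snap_tolerance_km,
                   seed = spec$seed),
              class = "region")
  })
}

# MST backbone over settlement points plus k-nearest shortcut edges;
# connected by construction
roads_random_planar <- function(villages, facilities, k_extra = 2) {
  pts <- rbind(cbind(villages$x_km, villages$y_km),
               cbind(facilities$x_km, facilities$y_km))
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 2) stop("need at least two distinct points for a road network",
                  call. = FALSE)
  d <- as.matrix(stats::dist(pts))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  el <- igraph::as_edgelist(mst, names = FALSE)
  edges <- unique(t(apply(el, 1, sort)))
  # shortcuts: each point to its k nearest neighbours
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:min(n, k_extra + 1)]
    edges <- rbind(edges, t(vapply(nb, function(j) sort(c(i, j)),
                                   numeric(2))))
  }
  edges <- unique(edges)
  data.frame(road_id = sprintf("R%05d", seq_len(nrow(edges))),
             x1 = pts[edges[, 1], 1], y1 = pts[edges[, 1], 2],
             x2 = pts[edges[, 2], 1], y2 = pts[edges[, 2], 2],
             length_km = d[edges],
             stringsAsFactors = FALSE)
}

# regular grid of roads with ~5 km spacing
roads_grid <- function(extent_km, spacing_km = 5) {
  k <- max(2, ceiling(extent_km / spacing_km) + 1)
  xs <- seq(0, extent_km, length.out = k)
  seg <- list()
  idx <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(k - 1)) {
      seg[[idx]] <- c(xs[j], xs[i], xs[j + 1], xs[i])  # horizontal
      idx <- idx + 1
      seg[[idx]] <- c(xs[i], xs[j], xs[i], xs[j + 1])  # vertical
      idx <- idx + 1
    }
  }
  s <- do.call(rbind, seg)
  data.frame(road_id = sprintf("R%05d", seq_len(nrow(s))),
             x1 = s[, 1], y1 = s[, 2], x2 = s[, 3], y2 = s[, 4],
             length_km = euclid(s[, 1], s[, 2], s[, 3], s[, 4]),
             stringsAsFactors = FALSE)
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf(paste0("<region> %d villages in %d blocks, %d facilities, ",
                     "%d road segments, %.0f km extent, pop %s\n"),
              nrow(x$villages), nrow(x$blocks), nrow(x$facilities),
              nrow(x$roads), x$extent_km,
              format(sum(x$villages$population), big.mark = ",")))
  invisible(x)
}

#' Road graph of a region
#'
#' Convenience wrapper: builds the attached [road_graph][build_graph] for a
#' region's villages and facilities.
#'
#' @param region a `region`.
#' @param snap_tolerance_km snap tolerance; defaults to the region's own.
#' @return a `road_graph`.
#' @export
region_graph <- function(region, snap_tolerance_km = NULL) {
  stopifnot(inherits(region, "region"))
  tol <- if (is.null(snap_tolerance_km)) region$snap_tolerance_km
         else snap_tolerance_km
  build_graph(region$roads, region$villages, region$facilities, tol)
}
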