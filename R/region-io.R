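# Minimal GeoJSON plumbing over jsonlite.  Coordinates are planar km (the
# synthetic frame carries no CRS); only Point and LineString features with
# flat property lists are needed.

geojson_write_points <- function(df, coords, props, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    p <- as.list(df[i, props, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df[[coords[1]]][i],
                                         df[[coords[2]]][i])),
         properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

geojson_write_segments <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(df$x1[i], df$y1[i]),
                                            c(df$x2[i], df$y2[i]))),
         properties = list(road_id = df$road_id[i],
                           length_km = df$length_km[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

geojson_read <- function(path, layer) {
  if (!file.exists(path)) {
    stop(sprintf("missing layer file: %s (%s)", basename(path), layer),
         call. = FALSE)
  }
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) {
                   stop(sprintf("cannot parse %s: %s", basename(path),
                                conditionMessage(e)), call. = FALSE)
                 })
  if (!identical(gj$type, "FeatureCollection") || is.null(gj$features)) {
    stop(sprintf("%s: not a GeoJSON FeatureCollection", basename(path)),
         call. = FALSE)
  }
  gj$features
}

feature_df <- function(features, geom_type, props, path) {
  rows <- lapply(seq_along(features), function(i) {
    ft <- features[[i]]
    if (!identical(ft$geometry$type, geom_type)) {
      stop(sprintf("%s: feature %d is not a %s", basename(path), i,
                   geom_type), call. = FALSE)
    }
    missing <- setdiff(props, names(ft$properties))
    if (length(missing) > 0) {
      stop(sprintf("%s: feature %d lacks propert%s %s", basename(path), i,
                   if (length(missing) > 1) "ies" else "y",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    c(ft$properties[props],
      if (geom_type == "Point") {
        list(x_km = ft$geometry$coordinates[[1]],
             y_km = ft$geometry$coordinates[[2]])
      } else {
        list(x1 = ft$geometry$coordinates[[1]][[1]],
             y1 = ft$geometry$coordinates[[1]][[2]],
             x2 = ft$geometry$coordinates[[2]][[1]],
             y2 = ft$geometry$coordinates[[2]][[2]])
      })
  })
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

#' Write a region to a directory of standard layers
#'
#' Writes `villages.geojson`, `facilities.geojson`, `roads.geojson` (planar
#' km coordinates) and `blocks.csv`, plus `region.json` with scalar metadata
#' (extent, snap tolerance, seed).  [read_region()] round-trips these
#' losslessly (coordinates to 1e-9 km).
#'
#' @param region a `region`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "region"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geojson_write_points(region$villages, c("x_km", "y_km"),
                       c("village_id", "name", "block_id", "population"),
                       file.path(dir, "villages.geojson"))
  geojson_write_points(region$facilities, c("x_km", "y_km"),
                       c("facility_id", "sector", "performs_csection",
                         "cy_enrolled", "obstetric_beds"),
                       file.path(dir, "facilities.geojson"))
  geojson_write_segments(region$roads, file.path(dir, "roads.geojson"))
  utils::write.csv(region$blocks, file.path(dir, "blocks.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(extent_km = region$extent_km,
                            snap_tolerance_km = region$snap_tolerance_km,
                            seed = region$seed),
                       file.path(dir, "region.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a region from a directory of standard layers
#'
#' Counterpart of [write_region()].  Errors name the missing layer file or
#' the offending record (e.g. a village referencing an unknown block id).
#'
#' @param dir directory containing `villages.geojson`, `facilities.geojson`,
#'   `roads.geojson`, `blocks.csv` and `region.json`.
#' @return a `region`.
#' @export
read_region <- function(dir) {
  vp <- file.path(dir, "villages.geojson")
  fp <- file.path(dir, "facilities.geojson")
  rp <- file.path(dir, "roads.geojson")
  bp <- file.path(dir, "blocks.csv")
  mp <- file.path(dir, "region.json")
  if (!file.exists(bp)) {
    stop("missing layer file: blocks.csv (blocks)", call. = FALSE)
  }
  if (!file.exists(mp)) {
    stop("missing layer file: region.json (metadata)", call. = FALSE)
  }
  villages <- feature_df(geojson_read(vp, "villages"), "Point",
                         c("village_id", "name", "block_id", "population"),
                         vp)
  facilities <- feature_df(geojson_read(fp, "facilities"), "Point",
                           c("facility_id", "sector", "performs_csection",
                             "cy_enrolled", "obstetric_beds"), fp)
  roads <- feature_df(geojson_read(rp, "roads"), "LineString",
                      c("road_id", "length_km"), rp)
  roads <- roads[, c("road_id", "x1", "y1", "x2", "y2", "length_km")]
  blocks <- utils::read.csv(bp, stringsAsFactors = FALSE)
  if (!all(c("block_id", "cbr_per_1000") %in% names(blocks))) {
    stop("blocks.csv must have columns block_id, cbr_per_1000",
         call. = FALSE)
  }
  unknown <- setdiff(villages$block_id, blocks$block_id)
  if (length(unknown) > 0) {
    bad <- villages$village_id[villages$block_id %in% unknown]
    stop(sprintf("villages.geojson: village(s) %s reference unknown block(s) %s",
                 paste(bad, collapse = ", "),
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  meta <- jsonlite::read_json(mp)
  villages <- villages[, c("village_id", "name", "block_id", "x_km", "y_km",
                           "population")]
  facilities <- facilities[, c("facility_id", "x_km", "y_km", "sector",
                               "performs_csection", "cy_enrolled",
                               "obstetric_beds")]
  facilities$obstetric_beds <- as.integer(facilities$obstetric_beds)
  structure(list(villages = villages, blocks = blocks,
                 facilities = facilities, roads = roads,
                 extent_km = meta$extent_km,
                 snap_tolerance_km = meta$snap_tolerance_km,
                 seed = meta$seed),
            class = "region")
}
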