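#' Build the road graph and attach villages and facilities
#'
#' Road segments are straight lines in a planar km frame; endpoints within
#' 1e-6 km of each other are fused into a single graph node.  Each village
#' and facility attaches to its nearest graph node via a connector of its
#' Euclidean offset (so a village 0.1 km from a node contributes 0.1 km to
#' every route), guaranteeing reachability and keeping distances exact down
#' to the last mile.  Offsets beyond `snap_tolerance_km` are flagged
#' `long_connector` in the attachments table for digitization QC; they do
#' not change the distances.  Entities that cannot reach each other after
#' attachment raise an error listing the disconnected ids.
#'
#' @param roads data frame of road segments: `x1, y1, x2, y2, length_km`
#'   (lengths must be positive; for straight digitized segments the length is
#'   the Euclidean endpoint distance, but any positive length is accepted).
#' @param villages data frame with `village_id, x_km, y_km` (may be empty).
#' @param facilities data frame with `facility_id, x_km, y_km` (may be empty).
#' @param snap_tolerance_km offset (km, default 2) beyond which an
#'   attachment is flagged as a long connector.
#' @return a `road_graph` object: igraph `graph` (edge weights in km),
#'   `nodes` (node coordinates) and `attachments` (entity id, kind, node,
#'   connector_km, long_connector).
#' @export
build_graph <- function(roads, villages, facilities, snap_tolerance_km = 2) {
  if (is.null(roads) || nrow(roads) == 0) {
    stop("road layer is empty: at least one road segment is required",
         call. = FALSE)
  }
  check_nonneg(snap_tolerance_km, "snap_tolerance_km")
  if (any(roads$length_km <= 0)) {
    stop("all road segment lengths must be > 0", call. = FALSE)
  }
  # fuse endpoints shared to within 1e-6 km
  pts <- rbind(cbind(roads$x1, roads$y1), cbind(roads$x2, roads$y2))
  key <- paste(round(pts[, 1] * 1e6), round(pts[, 2] * 1e6))
  node_key <- unique(key)
  node_id <- match(key, node_key)
  m <- nrow(roads)
  nodes <- data.frame(node = seq_along(node_key),
                      x_km = pts[match(node_key, key), 1],
                      y_km = pts[match(node_key, key), 2])
  from <- node_id[seq_len(m)]
  to <- node_id[m + seq_len(m)]
  if (any(from == to)) {
    stop("degenerate road segment with coincident endpoints", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = roads$length_km),
    directed = FALSE,
    vertices = data.frame(name = nodes$node))

  attach_one <- function(ids, xs, ys, kind) {
    if (length(ids) == 0) {
      return(data.frame(id = character(), kind = character(),
                        node = integer(), connector_km = numeric(),
                        long_connector = logical(),
                        stringsAsFactors = FALSE))
    }
    nearest <- integer(length(ids))
    conn <- numeric(length(ids))
    for (i in seq_along(ids)) {
      d <- euclid(xs[i], ys[i], nodes$x_km, nodes$y_km)
      j <- which.min(d)
      nearest[i] <- nodes$node[j]
      conn[i] <- d[j]
    }
    data.frame(id = as.character(ids), kind = kind, node = nearest,
               connector_km = conn,
               long_connector = conn > snap_tolerance_km,
               stringsAsFactors = FALSE)
  }
  att <- rbind(
    attach_one(villages$village_id, villages$x_km, villages$y_km, "village"),
    attach_one(facilities$facility_id, facilities$x_km, facilities$y_km,
               "facility"))
  if (anyDuplicated(att$id)) {
    stop("village and facility ids must be unique across both layers",
         call. = FALSE)
  }

  comp <- igraph::components(g)$membership
  att_comp <- comp[as.character(att$node)]
  if (nrow(att) > 0 && length(unique(att_comp)) > 1) {
    main <- names(which.max(table(att_comp)))
    stranded <- att$id[att_comp != main]
    stop(sprintf("entities disconnected from the road network: %s",
                 paste(stranded, collapse = ", ")), call. = FALSE)
  }

  structure(list(graph = g, nodes = nodes, attachments = att),
            class = "road_graph")
}

#' @export
print.road_graph <- function(x, ...) {
  cat(sprintf("<road_graph> %d nodes, %d edges, %d attached entities\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$attachments)))
  invisible(x)
}

#' Network shortest-path distances between attached entities
#'
#' Exact shortest-path (Dijkstra) kilometres between the listed source and
#' target entities, including any connector edges recorded at attachment
#' time.  When a `cutoff_km` is supplied, entries beyond it are stored as
#' `Inf`; the cutoff is kept on the result for downstream catchment logic.
#'
#' @param rg a `road_graph` from [build_graph()].
#' @param source_ids,target_ids character vectors of attached entity ids.
#' @param cutoff_km optional catchment cutoff in km (default `NULL`: keep all
#'   finite distances).
#' @return a `distance_matrix`: list with `km` (|sources| x |targets| matrix,
#'   dimnames = ids) and `cutoff_km`.
#' @export
shortest_distances <- function(rg, source_ids, target_ids, cutoff_km = NULL) {
  stopifnot(inherits(rg, "road_graph"))
  att <- rg$attachments
  miss <- setdiff(c(source_ids, target_ids), att$id)
  if (length(miss) > 0) {
    stop(sprintf("unknown entity id(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  si <- match(source_ids, att$id)
  ti <- match(target_ids, att$id)
  snodes <- att$node[si]
  tnodes <- att$node[ti]
  d_node <- igraph::distances(rg$graph,
                              v = as.character(unique(snodes)),
                              to = as.character(unique(tnodes)),
                              algorithm = "dijkstra")
  km <- d_node[match(as.character(snodes), rownames(d_node)),
               match(as.character(tnodes), colnames(d_node)), drop = FALSE]
  km <- km + outer(att$connector_km[si], att$connector_km[ti], `+`)
  dimnames(km) <- list(source_ids, target_ids)
  if (!is.null(cutoff_km)) {
    check_nonneg(cutoff_km, "cutoff_km")
    km[km > cutoff_km] <- Inf
  }
  structure(list(km = km, cutoff_km = cutoff_km), class = "distance_matrix")
}

#' Catchment of a facility
#'
#' All villages whose network distance to the facility is finite and at most
#' the cutoff.  The boundary is inclusive: a village at exactly the cutoff
#' distance belongs to the catchment.
#'
#' @param facility_id facility id (a column of the distance matrix).
#' @param distances a `distance_matrix` computed with a cutoff
#'   (rows = villages, columns = facilities).
#' @param cutoff_km optional override; defaults to the matrix's own cutoff.
#' @return character vector of village ids in the catchment.
#' @export
catchment <- function(facility_id, distances, cutoff_km = NULL) {
  stopifnot(inherits(distances, "distance_matrix"))
  if (!facility_id %in% colnames(distances$km)) {
    stop(sprintf("unknown facility id: %s", facility_id), call. = FALSE)
  }
  cut <- if (is.null(cutoff_km)) distances$cutoff_km else cutoff_km
  if (is.null(cut)) {
    stop("no cutoff available: supply 'cutoff_km' or compute the distance ",
         "matrix with one", call. = FALSE)
  }
  d <- distances$km[, facility_id]
  rownames(distances$km)[is.finite(d) & d <= cut]
}
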