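# Independent oracles, deliberately naive: exhaustive simple-path
# enumeration for shortest distances (no Dijkstra), direct subset
# evaluation for coverage.

# shortest distance between nodes s and t by enumerating every simple path
# (edges: data frame from, to, w over nodes 1..n)
brute_shortest <- function(edges, n, s, t) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; w <- edges$w[i]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  best <- Inf
  visited <- logical(n)
  dfs <- function(u, acc) {
    if (u == t) {
      best <<- min(best, acc)
      return()
    }
    if (acc >= best) return()
    visited[u] <<- TRUE
    nb <- adj[[u]]
    if (!is.null(nb)) {
      for (k in seq_len(nrow(nb))) {
        v <- nb[k, 1]
        if (!visited[v]) dfs(v, acc + nb[k, 2])
      }
    }
    visited[u] <<- FALSE
  }
  dfs(s, 0)
  best
}

# random connected planar-ish test graph: n points, random spanning tree
# plus a few extra edges, Euclidean lengths; returns roads df + node coords
random_road_graph <- function(n, extra = 3) {
  x <- runif(n, 0, 50)
  y <- runif(n, 0, 50)
  edges <- data.frame(from = integer(), to = integer())
  for (i in 2:n) {
    edges <- rbind(edges, data.frame(from = sample(i - 1, 1), to = i))
  }
  for (k in seq_len(extra)) {
    ab <- sort(sample(n, 2))
    edges <- rbind(edges, data.frame(from = ab[1], to = ab[2]))
  }
  edges <- unique(edges)
  edges$w <- sqrt((x[edges$from] - x[edges$to])^2 +
                    (y[edges$from] - y[edges$to])^2)
  edges <- edges[edges$w > 0, ]
  roads <- data.frame(road_id = sprintf("R%03d", seq_len(nrow(edges))),
                      x1 = x[edges$from], y1 = y[edges$from],
                      x2 = x[edges$to], y2 = y[edges$to],
                      length_km = edges$w, stringsAsFactors = FALSE)
  list(roads = roads, x = x, y = y, edges = edges, n = n)
}
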