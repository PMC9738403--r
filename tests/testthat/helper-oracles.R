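# Independent oracles and small fixtures used across the suite. These stay
# deliberately naive (brute force, enumeration) so they cannot share bugs
# with the package's optimised implementations.

# O(n^2) nearest-neighbour distances via a full distance matrix.
bf_nn_distances <- function(points) {
  dm <- as.matrix(stats::dist(cbind(points$x, points$y)))
  diag(dm) <- Inf
  unname(apply(dm, 1, min))
}

# Minimal facility spec for tests that only exercise other city components.
tiny_specs <- data.frame(class = "clinic", n = 2L, process = "uniform")

# Plain queue-based breadth-first search connectivity check.
bfs_connected <- function(n_nodes, from, to) {
  adj <- vector("list", n_nodes)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  seen <- logical(n_nodes)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

# Exhaustive simple-path enumeration: minimum cost from any source to every
# node. Exact on small graphs; no pruning beyond the simple-path rule.
bf_min_costs <- function(n_nodes, from, to, cost, sources, init = NULL) {
  if (is.null(init)) init <- rep(0, length(sources))
  adj <- vector("list", n_nodes)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- rbind(adj[[from[k]]], c(to[k], cost[k]))
    adj[[to[k]]] <- rbind(adj[[to[k]]], c(from[k], cost[k]))
  }
  best <- rep(Inf, n_nodes)
  dfs <- function(v, acc, visited) {
    if (acc < best[v]) best[v] <<- acc
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        dfs(w, acc + nb[r, 2], visited)
        visited[w] <- FALSE
      }
    }
  }
  for (s in seq_along(sources)) {
    visited <- logical(n_nodes)
    visited[sources[s]] <- TRUE
    dfs(sources[s], init[s], visited)
  }
  best
}

# Ray-casting point-in-polygon (handles any simple polygon); independent of
# the package's convex half-plane test.
ray_cast_inside <- function(poly, x, y) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > y) != (yj > y)
    xint <- (xj - xi) * (y - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (x < xint))
    j <- i
  }
  inside
}

# Build a multimodal walk graph from explicit node coordinates and an edge
# list with arbitrary positive lengths; returns the graph plus the mapping
# from test node index to graph node id.
toy_walk_graph <- function(coords, from, to, lengths,
                           params = network_params()) {
  edges <- tibble::tibble(
    x0 = coords[from, 1], y0 = coords[from, 2],
    x1 = coords[to, 1], y1 = coords[to, 2],
    length_m = lengths
  )
  g <- build_walk_graph(edges, params)
  key <- paste(round(coords[, 1], 2), round(coords[, 2], 2))
  gkey <- paste(round(g$nodes$x, 2), round(g$nodes$y, 2))
  list(graph = g, id = g$nodes$node[match(key, gkey)])
}

# Random sparse connected graph on n nodes: spanning tree plus extra edges.
random_small_graph <- function(n_nodes, n_extra = 3L) {
  coords <- cbind(runif(n_nodes, 0, 1000), runif(n_nodes, 0, 1000))
  from <- integer(0); to <- integer(0)
  for (v in 2:n_nodes) {
    from <- c(from, sample.int(v - 1L, 1L))
    to <- c(to, v)
  }
  for (k in seq_len(n_extra)) {
    pair <- sample.int(n_nodes, 2L)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  lengths <- runif(length(from), 10, 500)
  list(coords = coords, from = from, to = to, lengths = lengths)
}

# Compact synthetic-city preset used where the full default would be slow.
small_city_params <- function(seed = 42L) {
  city_params(
    seed = seed, grid_nx = 9L, grid_ny = 9L, block_spacing = 400,
    n_districts = 4L,
    pop_centers = data.frame(x = c(800, 2400), y = c(800, 2600),
                             total = c(4e4, 6e4), decay = c(700, 900)),
    facility_specs = data.frame(
      class = c("clinic", "pharmacy"), n = c(12L, 25L),
      process = "thomas", parents = c(3L, 4L), cluster_sd = c(400, 300)
    ),
    transit_specs = data.frame(
      line_id = c("r1", "b1"), mode = c("rail", "bus"),
      axis = c("row", "col"), index = c(5L, 5L),
      station_spacing = c(1600, 400)
    ),
    raster_cell = 200
  )
}
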