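# Multimodal travel-time graph: walking edges, station access links, and
# bus/rail ride edges with a fixed dwell impedance per stop. Stations are
# the transfer points between modes. Edge costs are seconds, lengths metres.

#' Travel-speed and network parameters
#'
#' Defaults: walking 1.2 m/s, bus 40 km/h, rail 70 km/h, 30 s dwell per
#' stop, 500 m station/facility snap tolerance. The driving speeds reflect
#' mountainous urban terrain.
#'
#' @param v_walk Walking speed, m/s.
#' @param v_bus_kmh Bus speed, km/h.
#' @param v_rail_kmh Rail speed, km/h.
#' @param dwell_s Stop (dwell) time added to every ride edge, seconds.
#' @param snap_tolerance Maximum distance allowed between a station or
#'   facility and its nearest walk node, metres.
#' @return A `network_params` object with speeds stored in m/s
#'   (`v_walk`, `v_bus`, `v_rail`), `dwell_s` and `snap_tolerance`.
#' @export
network_params <- function(v_walk = 1.2, v_bus_kmh = 40, v_rail_kmh = 70,
                           dwell_s = 30, snap_tolerance = 500) {
  if (any(c(v_walk, v_bus_kmh, v_rail_kmh) <= 0)) {
    abort("All speeds must be positive.")
  }
  if (dwell_s < 0) abort("`dwell_s` must be non-negative.")
  if (snap_tolerance <= 0) abort("`snap_tolerance` must be positive.")
  structure(
    list(v_walk = v_walk, v_bus = v_bus_kmh / 3.6, v_rail = v_rail_kmh / 3.6,
         dwell_s = dwell_s, snap_tolerance = snap_tolerance),
    class = "network_params"
  )
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf(
    "<network_params> walk %.2f m/s | bus %.1f km/h | rail %.1f km/h | dwell %g s | snap %g m\n",
    x$v_walk, x$v_bus * 3.6, x$v_rail * 3.6, x$dwell_s, x$snap_tolerance))
  invisible(x)
}

mode_speed <- function(params, mode) {
  switch(mode, bus = params$v_bus, rail = params$v_rail,
         abort(sprintf("Unknown transit mode '%s'.", mode)))
}

new_multimodal_graph <- function(nodes, edges, stations, params) {
  structure(list(nodes = nodes, edges = edges, stations = stations,
                 params = params),
            class = "multimodal_graph")
}

#' @export
print.multimodal_graph <- function(x, ...) {
  nn <- table(x$nodes$type)
  ne <- table(x$edges$type)
  fmt <- function(tt) paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", ")
  cat(sprintf("<multimodal_graph> %d nodes (%s)\n  %d edges (%s)\n",
              nrow(x$nodes), fmt(nn), nrow(x$edges), fmt(ne)))
  invisible(x)
}

# Directed igraph with both directions of every (symmetric-cost) edge;
# vertex names are node ids as character.
mm_igraph <- function(graph, extra_vertices = NULL, extra_edges = NULL) {
  e <- graph$edges[c("from", "to", "type", "length_m", "cost_s")]
  both <- dplyr::bind_rows(
    e, dplyr::rename(e, from = "to", to = "from")
  )
  both$from <- as.character(both$from)
  both$to <- as.character(both$to)
  if (!is.null(extra_edges)) both <- dplyr::bind_rows(both, extra_edges)
  verts <- c(as.character(graph$nodes$node), extra_vertices)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(both$from), to = as.character(both$to),
               weight = both$cost_s, type = both$type,
               length_m = both$length_m),
    directed = TRUE, vertices = data.frame(name = verts)
  )
}

# Nearest walk node for query points; returns tibble(node, snap_m).
nearest_walk_node <- function(graph, x, y) {
  wn <- graph$nodes[graph$nodes$type == "walk", ]
  node <- integer(length(x))
  snap <- numeric(length(x))
  for (i in seq_along(x)) {
    d2 <- (wn$x - x[i])^2 + (wn$y - y[i])^2
    j <- which.min(d2)
    node[i] <- wn$node[j]
    snap[i] <- sqrt(d2[j])
  }
  tibble(node = node, snap_m = snap)
}

#' Build the walking layer of a multimodal graph
#'
#' Turns road centreline segments into bidirectional walk edges with cost
#' `length / v_walk` seconds. Endpoints closer than 0.01 m are merged into
#' one node; segments with non-positive length are rejected and their ids
#' reported.
#'
#' @param walk_edges Data frame with columns `x0`, `y0`, `x1`, `y1`,
#'   `length_m` and optionally `edge_id` (see [make_grid_walk_network()]).
#' @param params A [network_params()] object.
#' @return A `multimodal_graph` holding the walk layer.
#' @export
build_walk_graph <- function(walk_edges, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  if (!all(c("x0", "y0", "x1", "y1", "length_m") %in% names(walk_edges))) {
    abort("`walk_edges` needs columns x0, y0, x1, y1, length_m.")
  }
  walk_edges <- as_tibble(walk_edges)
  if (!"edge_id" %in% names(walk_edges)) {
    walk_edges$edge_id <- sprintf("w%05d", seq_len(nrow(walk_edges)))
  }
  bad <- walk_edges$length_m <= 0
  if (any(bad)) {
    inform(sprintf("Rejected %d zero/negative-length walk edge(s): %s",
                   sum(bad),
                   paste(head(walk_edges$edge_id[bad], 10), collapse = ", ")))
    walk_edges <- walk_edges[!bad, ]
  }
  if (nrow(walk_edges) == 0) abort("No usable walk edges remain.")
  key <- function(x, y) paste(round(x * 100), round(y * 100))
  k0 <- key(walk_edges$x0, walk_edges$y0)
  k1 <- key(walk_edges$x1, walk_edges$y1)
  keys <- unique(c(k0, k1))
  id_of <- setNames(seq_along(keys), keys)
  first0 <- !duplicated(c(k0, k1))
  allx <- c(walk_edges$x0, walk_edges$x1)[first0]
  ally <- c(walk_edges$y0, walk_edges$y1)[first0]
  nodes <- tibble(
    node = seq_along(keys), x = allx, y = ally, type = "walk",
    station_id = NA_character_, line_id = NA_character_, mode = NA_character_
  )
  edges <- tibble(
    edge_id = walk_edges$edge_id,
    from = unname(id_of[k0]), to = unname(id_of[k1]),
    type = "walk",
    length_m = walk_edges$length_m,
    cost_s = walk_edges$length_m / params$v_walk,
    x0 = walk_edges$x0, y0 = walk_edges$y0,
    x1 = walk_edges$x1, y1 = walk_edges$y1
  )
  new_multimodal_graph(nodes, edges, stations = NULL, params = params)
}

#' Attach stations to the walk layer
#'
#' Creates one platform node per (station, line) and connects it to the
#' nearest walk node by a bidirectional access edge whose cost is the snap
#' distance walked at `v_walk`. Two lines calling at one location get two
#' platform nodes that transfer via the shared anchor walk node.
#'
#' @param graph A `multimodal_graph` from [build_walk_graph()].
#' @param stations Data frame with columns `station_id`, `line_id`, `mode`,
#'   `seq`, `x`, `y` (see [make_transit()]).
#' @param params Network parameters; defaults to those stored in `graph`.
#' @return The graph with platform nodes and access edges added; the
#'   snapped station table (with `anchor_node`, `snap_m`, `platform_node`)
#'   is stored as `graph$stations`.
#' @export
attach_stations <- function(graph, stations, params = graph$params) {
  stopifnot(inherits(graph, "multimodal_graph"))
  stations <- as_tibble(stations)
  need <- c("station_id", "line_id", "mode", "seq", "x", "y")
  if (!all(need %in% names(stations))) {
    abort(paste("`stations` needs columns", paste(need, collapse = ", ")))
  }
  snapped <- nearest_walk_node(graph, stations$x, stations$y)
  too_far <- snapped$snap_m > params$snap_tolerance
  if (any(too_far)) {
    abort(sprintf(
      "Station(s) beyond the %g m snap tolerance: %s",
      params$snap_tolerance,
      paste(stations$station_id[too_far], collapse = ", ")))
  }
  base <- max(graph$nodes$node)
  stations$platform_node <- base + seq_len(nrow(stations))
  stations$anchor_node <- snapped$node
  stations$snap_m <- snapped$snap_m
  platform_nodes <- tibble(
    node = stations$platform_node, x = stations$x, y = stations$y,
    type = "platform", station_id = stations$station_id,
    line_id = stations$line_id, mode = stations$mode
  )
  access_edges <- tibble(
    edge_id = sprintf("a_%s", stations$station_id),
    from = stations$platform_node, to = stations$anchor_node,
    type = "access",
    length_m = stations$snap_m,
    cost_s = stations$snap_m / params$v_walk,
    x0 = stations$x, y0 = stations$y,
    x1 = graph$nodes$x[match(stations$anchor_node, graph$nodes$node)],
    y1 = graph$nodes$y[match(stations$anchor_node, graph$nodes$node)]
  )
  new_multimodal_graph(
    dplyr::bind_rows(graph$nodes, platform_nodes),
    dplyr::bind_rows(graph$edges, access_edges),
    stations = stations, params = params
  )
}

# Cumulative arc-length position of points projected onto a polyline
# (n x 2 matrix of vertices). Used for along-alignment ride distances.
polyline_arc_position <- function(poly, x, y) {
  nseg <- nrow(poly) - 1L
  if (nseg < 1) abort("An alignment polyline needs at least 2 vertices.")
  seg_len <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  cum0 <- c(0, cumsum(seg_len))[seq_len(nseg)]
  pos <- numeric(length(x))
  for (i in seq_along(x)) {
    best <- Inf; best_pos <- 0
    for (s in seq_len(nseg)) {
      dx <- poly[s + 1, 1] - poly[s, 1]; dy <- poly[s + 1, 2] - poly[s, 2]
      l2 <- dx * dx + dy * dy
      t <- if (l2 == 0) 0 else
        max(0, min(1, ((x[i] - poly[s, 1]) * dx + (y[i] - poly[s, 2]) * dy) / l2))
      d <- sqrt((x[i] - (poly[s, 1] + t * dx))^2 + (y[i] - (poly[s, 2] + t * dy))^2)
      if (d < best) { best <- d; best_pos <- cum0[s] + t * seg_len[s] }
    }
    pos[i] <- best_pos
  }
  pos
}

#' Add bus/rail ride edges between consecutive stations
#'
#' For every consecutive station pair of each line, adds bidirectional ride
#' edges between the platform nodes with cost
#' `distance / v_mode + dwell_s`: the dwell models the stop-time impedance,
#' so boarding at the first station costs no dwell and each traversed stop
#' costs one. Distance is Euclidean between stations, or measured along the
#' line's alignment polyline when one is supplied.
#'
#' @param graph A `multimodal_graph` with stations attached.
#' @param params Network parameters; defaults to those stored in `graph`.
#' @param alignments Optional named list, `line_id` to an `n x 2` polyline
#'   matrix; inter-station distance is then along-alignment.
#' @return The graph with ride edges added.
#' @export
add_ride_edges <- function(graph, params = graph$params, alignments = NULL) {
  stopifnot(inherits(graph, "multimodal_graph"))
  st <- graph$stations
  if (is.null(st) || nrow(st) == 0) {
    abort("No stations attached; call attach_stations() first.")
  }
  singles <- dplyr::count(st, .data$line_id) |> dplyr::filter(.data$n < 2)
  if (nrow(singles) > 0) {
    abort(sprintf("Line(s) with fewer than 2 stations rejected: %s",
                  paste(singles$line_id, collapse = ", ")))
  }
  ride <- st |>
    dplyr::arrange(.data$line_id, .data$seq) |>
    dplyr::group_by(.data$line_id) |>
    dplyr::group_modify(function(d, key) {
      line <- key$line_id[[1]]
      k <- nrow(d)
      if (!is.null(alignments) && line %in% names(alignments)) {
        pos <- polyline_arc_position(alignments[[line]], d$x, d$y)
        dist <- abs(diff(pos))
        straight <- sqrt(diff(d$x)^2 + diff(d$y)^2)
        if (any(dist < straight - 1e-6)) {
          abort(sprintf(
            "Alignment of line '%s' is shorter than the straight-line station distance.",
            line))
        }
      } else {
        dist <- sqrt(diff(d$x)^2 + diff(d$y)^2)
      }
      if (any(dist == 0)) {
        abort(sprintf("Line '%s' has coincident consecutive stations.", line))
      }
      v <- mode_speed(graph$params, d$mode[1])
      tibble(
        edge_id = sprintf("r_%s_%02d", line, seq_len(k - 1)),
        from = d$platform_node[-k], to = d$platform_node[-1],
        type = "ride",
        length_m = dist,
        cost_s = dist / v + graph$params$dwell_s,
        x0 = d$x[-k], y0 = d$y[-k], x1 = d$x[-1], y1 = d$y[-1]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::select(!"line_id")
  new_multimodal_graph(graph$nodes, dplyr::bind_rows(graph$edges, ride),
                       graph$stations, params)
}

#' Build the full multimodal graph of a synthetic city
#'
#' Convenience wrapper: [build_walk_graph()], [attach_stations()],
#' [add_ride_edges()].
#'
#' @param city A [synthetic_city()] object.
#' @param params A [network_params()] object.
#' @return A `multimodal_graph`.
#' @export
build_multimodal_graph <- function(city, params = network_params()) {
  stopifnot(inherits(city, "synthetic_city"))
  build_walk_graph(city$walk_edges, params) |>
    attach_stations(city$stations) |>
    add_ride_edges()
}

#' Diagnostic report on a multimodal graph
#'
#' Counts nodes and edges by type, connected components of the walk layer,
#' orphan platform nodes (no access edge) and negative-cost edges (there
#' must be none).
#'
#' @param graph A `multimodal_graph`.
#' @return A list of class `graph_report` with fields `node_counts`,
#'   `edge_counts`, `walk_components`, `orphan_platforms`,
#'   `negative_costs`.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "multimodal_graph"))
  node_counts <- table(graph$nodes$type)
  edge_counts <- if (nrow(graph$edges)) table(graph$edges$type) else table(character(0))
  walk_nodes <- graph$nodes$node[graph$nodes$type == "walk"]
  walk_edges <- graph$edges[graph$edges$type == "walk", ]
  walk_components <- if (length(walk_nodes) == 0) {
    0L
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(walk_edges$from),
                 to = as.character(walk_edges$to)),
      directed = FALSE,
      vertices = data.frame(name = as.character(walk_nodes)))
    igraph::count_components(g)
  }
  platforms <- graph$nodes$node[graph$nodes$type == "platform"]
  access <- graph$edges[graph$edges$type == "access", ]
  orphan <- setdiff(platforms, c(access$from, access$to))
  structure(
    list(node_counts = node_counts, edge_counts = edge_counts,
         walk_components = walk_components,
         orphan_platforms = length(orphan),
         negative_costs = sum(graph$edges$cost_s < 0)),
    class = "graph_report"
  )
}

#' @export
print.graph_report <- function(x, ...) {
  fmt <- function(tt) {
    if (length(tt) == 0) return("none")
    paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", ")
  }
  cat("<graph_report>\n")
  cat("  nodes:", fmt(x$node_counts), "\n")
  cat("  edges:", fmt(x$edge_counts), "\n")
  cat(sprintf("  walk components: %d | orphan platforms: %d | negative costs: %d\n",
              x$walk_components, x$orphan_platforms, x$negative_costs))
  invisible(x)
}
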