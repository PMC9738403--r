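# Isochrone service areas from facility points and the district-level
# accessibility ratios: SAR = sa/ta (service area over district area) and
# SPR = sp/tp (service population over district population).

#' Service-area configuration
#'
#' @param thresholds_min Travel-time thresholds in minutes, strictly
#'   increasing; default 15/30/60.
#' @param buffer_width Half-width in metres of the buffer drawn around
#'   reached street portions when polygonising a service area.
#' @return An `access_config` object.
#' @export
access_config <- function(thresholds_min = c(15, 30, 60), buffer_width = 50) {
  if (!is.numeric(thresholds_min) || length(thresholds_min) < 1 ||
      any(thresholds_min <= 0) || is.unsorted(thresholds_min, strictly = TRUE)) {
    abort("`thresholds_min` must be strictly increasing positive minutes.")
  }
  if (!is.numeric(buffer_width) || buffer_width <= 0) {
    abort("`buffer_width` must be positive.")
  }
  structure(list(thresholds_min = thresholds_min, buffer_width = buffer_width),
            class = "access_config")
}

#' @export
print.access_config <- function(x, ...) {
  cat(sprintf("<access_config> thresholds %s min | buffer %g m\n",
              paste(x$thresholds_min, collapse = "/"), x$buffer_width))
  invisible(x)
}

#' Snap facilities onto the walk network as routing sources
#'
#' Each facility is mapped to its nearest walk node with an initial cost
#' equal to the snap distance walked at `v_walk`. Facilities farther than
#' the snap tolerance are excluded with a warning (and counted in the
#' `excluded` attribute).
#'
#' @param facilities Data frame with columns `x`, `y` (one facility per
#'   row).
#' @param graph A `multimodal_graph`.
#' @param params Network parameters; defaults to those stored in `graph`.
#' @return A tibble with columns `x`, `y`, `node`, `snap_m`, `init_cost_s`.
#' @export
facility_sources <- function(facilities, graph, params = graph$params) {
  check_points(facilities, min_n = 1L, what = "facilities")
  snapped <- nearest_walk_node(graph, facilities$x, facilities$y)
  keep <- snapped$snap_m <= params$snap_tolerance
  if (!all(keep)) {
    warn(sprintf("%d facility(ies) beyond the %g m snap tolerance were excluded.",
                 sum(!keep), params$snap_tolerance))
  }
  out <- tibble(
    x = facilities$x[keep], y = facilities$y[keep],
    node = snapped$node[keep], snap_m = snapped$snap_m[keep],
    init_cost_s = snapped$snap_m[keep] / params$v_walk
  )
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Travel-time reach from multiple sources
#'
#' Runs a shortest-path (Dijkstra) expansion from all sources
#' simultaneously (via a zero-cost virtual super-source carrying each
#' source's initial cost) and records, for every edge, the fraction covered
#' within the time budget. A walk or access edge is fully covered when it
#' can be traversed from either end within the budget, and partially
#' covered up to the remaining budget converted to distance at that edge's
#' speed; ride edges are all-or-nothing, since passengers can only alight
#' at stations.
#'
#' @param graph A `multimodal_graph`.
#' @param sources Tibble from [facility_sources()] (columns `node`,
#'   `init_cost_s`), or a vector of node ids (initial cost 0).
#' @param budget_s Time budget in seconds (> 0).
#' @return A `reach` object: `node_cost` (tibble `node`, `cost_s`,
#'   `reached`), `edges` (per-edge coverage fractions `frac_from`,
#'   `frac_to`, `covered_frac`), `segments` (covered walk/access portions
#'   as coordinate rows) and `budget_s`.
#' @export
multi_source_reach <- function(graph, sources, budget_s) {
  stopifnot(inherits(graph, "multimodal_graph"))
  if (is.numeric(sources) && is.null(dim(sources))) {
    sources <- tibble(node = as.integer(sources), init_cost_s = 0)
  }
  if (!is.data.frame(sources) || nrow(sources) == 0) {
    abort("`sources` must be a non-empty source table or node vector.")
  }
  if (!"init_cost_s" %in% names(sources)) sources$init_cost_s <- 0
  if (!is.numeric(budget_s) || length(budget_s) != 1 || budget_s <= 0) {
    abort("`budget_s` must be a single positive number of seconds.")
  }
  src_edges <- tibble(
    from = "SRC", to = as.character(sources$node),
    type = "source", length_m = 0, cost_s = sources$init_cost_s
  )
  g <- mm_igraph(graph, extra_vertices = "SRC", extra_edges = src_edges)
  d <- igraph::distances(g, v = "SRC", mode = "out",
                         weights = igraph::E(g)$weight)[1, ]
  node_ids <- graph$nodes$node
  cost <- unname(d[as.character(node_ids)])
  node_cost <- tibble(node = node_ids, cost_s = cost,
                      reached = cost <= budget_s)
  e <- graph$edges
  du <- cost[match(e$from, node_ids)]
  dv <- cost[match(e$to, node_ids)]
  slack_u <- budget_s - du
  slack_v <- budget_s - dv
  clamp01 <- function(z) pmin(1, pmax(0, z))
  frac_from <- ifelse(e$type == "ride",
                      as.numeric(slack_u >= e$cost_s),
                      clamp01(slack_u / e$cost_s))
  frac_to <- ifelse(e$type == "ride",
                    as.numeric(slack_v >= e$cost_s),
                    clamp01(slack_v / e$cost_s))
  covered <- pmin(1, frac_from + frac_to)
  edges <- dplyr::mutate(e, frac_from = frac_from, frac_to = frac_to,
                         covered_frac = covered)
  walkish <- edges[edges$type %in% c("walk", "access") & edges$covered_frac > 0, ]
  segs <- vector("list", 3L)
  full <- walkish[walkish$covered_frac >= 1, ]
  if (nrow(full)) {
    segs[[1]] <- tibble(x0 = full$x0, y0 = full$y0, x1 = full$x1, y1 = full$y1)
  }
  part <- walkish[walkish$covered_frac < 1, ]
  if (nrow(part)) {
    f <- part[part$frac_from > 0, ]
    if (nrow(f)) {
      segs[[2]] <- tibble(
        x0 = f$x0, y0 = f$y0,
        x1 = f$x0 + f$frac_from * (f$x1 - f$x0),
        y1 = f$y0 + f$frac_from * (f$y1 - f$y0)
      )
    }
    t <- part[part$frac_to > 0, ]
    if (nrow(t)) {
      segs[[3]] <- tibble(
        x0 = t$x1, y0 = t$y1,
        x1 = t$x1 + t$frac_to * (t$x0 - t$x1),
        y1 = t$y1 + t$frac_to * (t$y0 - t$y1)
      )
    }
  }
  segments <- dplyr::bind_rows(segs)
  structure(
    list(budget_s = budget_s, node_cost = node_cost, edges = edges,
         segments = segments, n_sources = nrow(sources)),
    class = "reach"
  )
}

#' @export
print.reach <- function(x, ...) {
  cat(sprintf(
    "<reach> budget %g s from %d source(s): %d/%d nodes reached, %.1f of %d edges covered\n",
    x$budget_s, x$n_sources, sum(x$node_cost$reached), nrow(x$node_cost),
    sum(x$edges$covered_frac), nrow(x$edges)))
  invisible(x)
}

#' Buffer the reached street portions into a coverage region
#'
#' The service area is the union of round-capped buffers of width
#' `buffer_width` around every covered walk/access edge portion; ride
#' (in-vehicle) segments contribute reachability but no geometry. The
#' region is represented implicitly (membership = within `buffer_width` of
#' a covered portion), which keeps nesting across budgets exact; areas are
#' measured by cell-centre quadrature ([region_area()]) and outlines are
#' available via [coverage_outline()].
#'
#' @param reach A `reach` object (or a data frame of segments with columns
#'   `x0`, `y0`, `x1`, `y1`).
#' @param buffer_width Buffer half-width in metres.
#' @return A `coverage` region object.
#' @export
coverage_polygon <- function(reach, buffer_width = 50) {
  if (!is.numeric(buffer_width) || buffer_width <= 0) {
    abort("`buffer_width` must be positive.")
  }
  segments <- if (inherits(reach, "reach")) reach$segments else as_tibble(reach)
  if (!is.null(segments) && nrow(segments) > 0 &&
      !all(c("x0", "y0", "x1", "y1") %in% names(segments))) {
    abort("Segments need columns x0, y0, x1, y1.")
  }
  structure(list(segments = segments %||% tibble(), width = buffer_width),
            class = c("coverage", "region"))
}

#' @export
region_contains.coverage <- function(region, x, y) {
  inside <- rep(FALSE, length(x))
  s <- region$segments
  if (is.null(s) || nrow(s) == 0) return(inside)
  w <- region$width
  for (i in seq_len(nrow(s))) {
    xlo <- min(s$x0[i], s$x1[i]) - w; xhi <- max(s$x0[i], s$x1[i]) + w
    ylo <- min(s$y0[i], s$y1[i]) - w; yhi <- max(s$y0[i], s$y1[i]) + w
    cand <- which(!inside & x >= xlo & x <= xhi & y >= ylo & y <= yhi)
    if (length(cand)) {
      inside[cand] <- dist_point_segment(x[cand], y[cand],
                                         s$x0[i], s$y0[i],
                                         s$x1[i], s$y1[i]) <= w
    }
  }
  inside
}

#' @export
print.coverage <- function(x, ...) {
  cat(sprintf("<coverage> %d buffered segment(s), width %g m\n",
              nrow(x$segments), x$width))
  invisible(x)
}

#' Discretised outline polygons of a coverage region
#'
#' One round-capped buffer polygon (stadium) per covered segment, with arcs
#' discretised at `n_arc` vertices per semicircle. Polygons of overlapping
#' segments overlap; they are meant for display and GeoJSON export, while
#' areas should be measured with [region_area()].
#'
#' @param coverage A `coverage` object.
#' @param n_arc Vertices per semicircular cap.
#' @return A list of `n x 2` vertex matrices.
#' @export
coverage_outline <- function(coverage, n_arc = 16L) {
  s <- coverage$segments
  w <- coverage$width
  if (is.null(s) || nrow(s) == 0) return(list())
  lapply(seq_len(nrow(s)), function(i) {
    dx <- s$x1[i] - s$x0[i]; dy <- s$y1[i] - s$y0[i]
    len <- sqrt(dx^2 + dy^2)
    ang <- if (len == 0) 0 else atan2(dy, dx)
    t1 <- ang + pi / 2 + seq(0, pi, length.out = n_arc)   # cap at end 1
    t0 <- ang - pi / 2 + seq(0, pi, length.out = n_arc)   # cap at end 0
    cbind(
      c(s$x1[i] + w * cos(t1), s$x0[i] + w * cos(t0)),
      c(s$y1[i] + w * sin(t1), s$y0[i] + w * sin(t0))
    )
  })
}

district_geometry <- function(district) {
  if (is.matrix(district)) return(district)
  if (is.data.frame(district) && "geometry" %in% names(district)) {
    if (nrow(district) != 1) abort("Pass a single district row.")
    return(district$geometry[[1]])
  }
  abort("`district` must be a vertex matrix or a one-row district tibble.")
}

#' Service-area ratio of a district
#'
#' `SAR = sa / ta`: the fraction of the district's area lying inside the
#' service-area region. Both areas are measured with the same cell-centre
#' rule on a grid over the district's bounding box, so a region containing
#' the district gives exactly 1.
#'
#' @param region A region object (e.g. from [coverage_polygon()]).
#' @param district District polygon: an `n x 2` vertex matrix or a one-row
#'   tibble with a `geometry` list column.
#' @param cell_size Quadrature cell size in metres.
#' @return The ratio in `[0, 1]`.
#' @export
sar <- function(region, district, cell_size = 100) {
  poly <- district_geometry(district)
  if (polygon_area(poly) <= 0) abort("Degenerate district polygon.")
  ext <- bbox_extent(poly[, 1], poly[, 2])
  nx <- max(1L, as.integer(ceiling(extent_width(ext) / cell_size)))
  ny <- max(1L, as.integer(ceiling(extent_height(ext) / cell_size)))
  csx <- extent_width(ext) / nx
  csy <- extent_height(ext) / ny
  cx <- ext[["xmin"]] + (seq_len(nx) - 0.5) * csx
  cy <- ext[["ymin"]] + (seq_len(ny) - 0.5) * csy
  pts <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  in_d <- point_in_convex(poly, pts$x, pts$y)
  if (!any(in_d)) abort("No quadrature cell centre falls inside the district.")
  sum(region_contains(region, pts$x[in_d], pts$y[in_d])) / sum(in_d)
}

#' Service-population ratio of a district
#'
#' `SPR = sp / tp`: the fraction of the district's population (raster cells
#' whose centres fall in the district) living inside the service-area
#' region.
#'
#' @param region A region object.
#' @param raster A `pop_raster`.
#' @param district District polygon (matrix or one-row tibble).
#' @return The ratio in `[0, 1]`, or `NA` when the district holds no
#'   population.
#' @export
spr <- function(region, raster, district) {
  poly <- district_geometry(district)
  cells <- raster_cells(raster)
  in_d <- point_in_convex(poly, cells$x, cells$y)
  tp <- sum(cells$pop[in_d])
  if (tp <= 0) {
    inform("District holds no population; SPR is undefined (NA).")
    return(NA_real_)
  }
  in_r <- region_contains(region, cells$x[in_d], cells$y[in_d])
  sum(cells$pop[in_d][in_r]) / tp
}

#' District-level accessibility of every facility class
#'
#' For each facility class, computes the multi-source isochrone at each
#' threshold (one reach per class and threshold, from the union of the
#' class's snapped facilities), buffers it into a coverage region, and
#' evaluates SAR and SPR per district on the population-raster grid: `ta`
#' and `tp` are the area and population of the district's cells, `sa` and
#' `sp` the covered subsets. Per-district and per-class averages are
#' arithmetic means of the ratios.
#'
#' @param city A [synthetic_city()] object (or any list with `facilities`,
#'   `districts`, `population` of the same shapes).
#' @param graph The city's `multimodal_graph`.
#' @param config An [access_config()] object.
#' @return An `access_table` object: `records` (district x class x
#'   threshold tibble with `sa_m2`, `ta_m2`, `sp`, `tp`, `SAR`, `SPR`),
#'   `by_district` and `by_class` average tibbles, and the isochrone
#'   coverages.
#' @export
run_accessibility <- function(city, graph, config = access_config()) {
  stopifnot(inherits(graph, "multimodal_graph"))
  stopifnot(inherits(config, "access_config"))
  cells <- raster_cells(city$population)
  cell_area <- city$population$cell_size^2
  cells$district <- district_of(city$districts, cells$x, cells$y)
  base <- cells |>
    dplyr::summarise(ta_m2 = dplyr::n() * cell_area, tp = sum(.data$pop),
                     .by = "district")
  classes <- unique(city$facilities$class)
  records <- list()
  coverages <- list()
  for (cl in classes) {
    fac <- city$facilities[city$facilities$class == cl, ]
    if (nrow(fac) == 0) next
    sources <- facility_sources(fac, graph)
    for (thr in config$thresholds_min) {
      reach <- multi_source_reach(graph, sources, budget_s = thr * 60)
      cov <- coverage_polygon(reach, config$buffer_width)
      key <- sprintf("%s_%gmin", cl, thr)
      coverages[[key]] <- cov
      covered <- region_contains(cov, cells$x, cells$y)
      per_d <- cells |>
        dplyr::mutate(covered = covered) |>
        dplyr::summarise(
          sa_m2 = sum(.data$covered) * cell_area,
          sp = sum(.data$pop[.data$covered]),
          .by = "district"
        )
      rec <- base |>
        dplyr::left_join(per_d, by = "district") |>
        dplyr::mutate(
          sa_m2 = dplyr::coalesce(.data$sa_m2, 0),
          sp = dplyr::coalesce(.data$sp, 0),
          class = cl, threshold_min = thr,
          SAR = .data$sa_m2 / .data$ta_m2,
          SPR = ifelse(.data$tp > 0, .data$sp / .data$tp, NA_real_)
        )
      records[[key]] <- rec
    }
  }
  records <- dplyr::bind_rows(records)[
    , c("district", "class", "threshold_min",
        "sa_m2", "ta_m2", "sp", "tp", "SAR", "SPR")]
  by_district <- records |>
    dplyr::summarise(SAR = mean(.data$SAR), SPR = mean(.data$SPR, na.rm = TRUE),
                     .by = c("district", "threshold_min"))
  by_class <- records |>
    dplyr::summarise(SAR = mean(.data$SAR), SPR = mean(.data$SPR, na.rm = TRUE),
                     .by = c("class", "threshold_min"))
  structure(
    list(records = records, by_district = by_district, by_class = by_class,
         coverages = coverages, config = config),
    class = "access_table"
  )
}

#' @export
print.access_table <- function(x, ...) {
  cat(sprintf("<access_table> %d records (%d districts x %d classes x %d thresholds)\n",
              nrow(x$records), length(unique(x$records$district)),
              length(unique(x$records$class)),
              length(unique(x$records$threshold_min))))
  print(x$by_class)
  invisible(x)
}

#' Tidy an accessibility table
#'
#' @param x An `access_table` object.
#' @param ... Unused.
#' @return The per-district records tibble.
#' @method tidy access_table
#' @export
tidy.access_table <- function(x, ...) x$records

#' @rdname tidy.access_table
#' @method glance access_table
#' @export
glance.access_table <- function(x, ...) {
  x$records |>
    dplyr::summarise(mean_SAR = mean(.data$SAR),
                     mean_SPR = mean(.data$SPR, na.rm = TRUE),
                     .by = "threshold_min")
}

#' @method autoplot access_table
#' @export
autoplot.access_table <- function(object, metric = c("SPR", "SAR"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(
    object$records,
    ggplot2::aes(.data$district, .data[[metric]],
                 fill = factor(.data$threshold_min))
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, fill = "threshold (min)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
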