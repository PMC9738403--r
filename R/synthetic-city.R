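# Synthetic study regions: a grid walk network, transit corridors with
# stations, a multi-centre population raster, Voronoi districts, and
# facility point patterns spanning the clustered-to-dispersed range. All
# coordinates are planar metres.

#' Parameters of a synthetic city
#'
#' Bundles every knob of the synthetic-city generator. The defaults describe
#' a polycentric city of about 12 x 12 km with a 500 m street grid, nine
#' districts, three population centres totalling one million residents, two
#' rail lines crossing at the centre, four bus lines, and six medical
#' facility classes whose point processes range from strongly clustered
#' (pharmacies, clinics) to comparatively dispersed (community hospitals).
#'
#' @param seed Integer seed; the whole city is a deterministic function of
#'   the parameters and this seed.
#' @param grid_nx,grid_ny Number of street-grid intersections per axis
#'   (so the extent spans `(grid_nx - 1) * block_spacing` metres east-west).
#' @param block_spacing Street block length in metres.
#' @param n_districts Number of Voronoi districts partitioning the extent.
#' @param pop_centers Data frame with columns `x`, `y`, `total`, `decay`:
#'   Gaussian population centres (persons) with decay length in metres.
#' @param facility_specs Data frame with columns `class`, `n`, `process`
#'   (`"uniform"`, `"thomas"` or `"lattice"`), `parents`, `cluster_sd`.
#' @param transit_specs Data frame with columns `line_id`, `mode`
#'   (`"bus"`/`"rail"`), `axis` (`"row"`/`"col"`), `index` (1-based gridline
#'   index of the corridor), `station_spacing` (metres).
#' @param raster_cell Population raster cell size in metres; must divide the
#'   extent dimensions.
#' @return An object of class `city_params`.
#' @export
city_params <- function(seed = 1L,
                        grid_nx = 25L, grid_ny = 25L,
                        block_spacing = 500,
                        n_districts = 9L,
                        pop_centers = NULL,
                        facility_specs = NULL,
                        transit_specs = NULL,
                        raster_cell = 250) {
  if (grid_nx < 2 || grid_ny < 2) abort("`grid_nx` and `grid_ny` must be >= 2.")
  if (!is.numeric(block_spacing) || block_spacing <= 0) {
    abort("`block_spacing` must be a positive number of metres.")
  }
  if (n_districts < 1) abort("`n_districts` must be positive.")
  width <- (grid_nx - 1) * block_spacing
  height <- (grid_ny - 1) * block_spacing
  extent <- as_extent(c(0, 0, width, height))

  if (is.null(pop_centers)) {
    pop_centers <- tibble(
      x = c(0.30, 0.70, 0.35) * width,
      y = c(0.30, 0.65, 0.80) * height,
      total = c(4e5, 3e5, 3e5),
      decay = c(2000, 2500, 2000)
    )
  }
  pop_centers <- as_tibble(pop_centers)
  stopifnot(all(c("x", "y", "total", "decay") %in% names(pop_centers)))
  if (nrow(pop_centers) < 1) abort("At least one population centre is required.")
  if (any(pop_centers$total <= 0) || any(pop_centers$decay <= 0)) {
    abort("Population centre totals and decay lengths must be positive.")
  }

  if (is.null(facility_specs)) {
    facility_specs <- tibble(
      class = c("tertiary_A", "general", "specialist",
                "community", "clinic", "pharmacy"),
      n = c(8L, 40L, 30L, 60L, 150L, 300L),
      process = "thomas",
      parents = c(3L, 6L, 5L, 12L, 10L, 12L),
      cluster_sd = c(900, 1200, 900, 1800, 1000, 700)
    )
  }
  facility_specs <- as_tibble(facility_specs)
  stopifnot(all(c("class", "n", "process") %in% names(facility_specs)))
  if (!"parents" %in% names(facility_specs)) facility_specs$parents <- 5L
  if (!"cluster_sd" %in% names(facility_specs)) facility_specs$cluster_sd <- NA_real_
  if (any(facility_specs$n <= 0)) abort("Facility counts must be positive.")
  bad_sd <- !is.na(facility_specs$cluster_sd) & facility_specs$cluster_sd >= width
  if (any(bad_sd)) abort("`cluster_sd` must be smaller than the extent width.")

  if (is.null(transit_specs)) {
    mid_r <- as.integer(ceiling(grid_ny / 2))
    mid_c <- as.integer(ceiling(grid_nx / 2))
    q_r <- pmax(1L, as.integer(round(c(0.25, 0.75) * grid_ny)))
    q_c <- pmax(1L, as.integer(round(c(0.25, 0.75) * grid_nx)))
    transit_specs <- tibble(
      line_id = c("rail_1", "rail_2", "bus_1", "bus_2", "bus_3", "bus_4"),
      mode = c("rail", "rail", "bus", "bus", "bus", "bus"),
      axis = c("row", "col", "row", "row", "col", "col"),
      index = c(mid_r, mid_c, q_r[1], q_r[2], q_c[1], q_c[2]),
      station_spacing = c(1500, 1500, 500, 500, 500, 500)
    )
  }
  transit_specs <- as_tibble(transit_specs)
  stopifnot(all(c("line_id", "mode", "axis", "index", "station_spacing") %in%
                  names(transit_specs)))
  if (!all(transit_specs$mode %in% c("bus", "rail"))) {
    abort("Transit modes must be 'bus' or 'rail'.")
  }
  if (!all(transit_specs$axis %in% c("row", "col"))) {
    abort("Transit axes must be 'row' or 'col'.")
  }
  n_lines <- ifelse(transit_specs$axis == "row", grid_ny, grid_nx)
  if (any(transit_specs$index < 1 | transit_specs$index > n_lines)) {
    abort("Transit corridor `index` must lie within the grid.")
  }
  if (any(transit_specs$station_spacing < block_spacing)) {
    abort("`station_spacing` must be at least `block_spacing`.")
  }

  if (!is.numeric(raster_cell) || raster_cell <= 0) {
    abort("`raster_cell` must be positive.")
  }
  if (abs(width / raster_cell - round(width / raster_cell)) > 1e-9 ||
      abs(height / raster_cell - round(height / raster_cell)) > 1e-9) {
    abort("`raster_cell` must divide the extent dimensions exactly.")
  }

  structure(
    list(
      seed = as.integer(seed),
      grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
      block_spacing = block_spacing,
      extent = extent,
      n_districts = as.integer(n_districts),
      pop_centers = pop_centers,
      facility_specs = facility_specs,
      transit_specs = transit_specs,
      raster_cell = raster_cell
    ),
    class = "city_params"
  )
}

#' @export
print.city_params <- function(x, ...) {
  cat("<city_params>\n")
  cat(sprintf("  extent: %.0f x %.0f m, grid %d x %d (block %g m)\n",
              extent_width(x$extent), extent_height(x$extent),
              x$grid_nx, x$grid_ny, x$block_spacing))
  cat(sprintf("  districts: %d | population centres: %d (total %s persons)\n",
              x$n_districts, nrow(x$pop_centers),
              format(sum(x$pop_centers$total), big.mark = ",")))
  cat(sprintf("  facility classes: %s\n",
              paste(x$facility_specs$class, collapse = ", ")))
  cat(sprintf("  transit lines: %d (%d rail, %d bus) | seed %d\n",
              nrow(x$transit_specs), sum(x$transit_specs$mode == "rail"),
              sum(x$transit_specs$mode == "bus"), x$seed))
  invisible(x)
}

#' Street-grid walking network
#'
#' Returns the edges of a `grid_nx` x `grid_ny` lattice of intersections
#' spaced `block_spacing` apart; every edge carries its Euclidean length.
#' A lattice has `2 * nx * ny - nx - ny` edges and is connected.
#'
#' @param params A [city_params()] object.
#' @return A tibble with columns `edge_id`, `x0`, `y0`, `x1`, `y1`,
#'   `length_m`.
#' @export
make_grid_walk_network <- function(params) {
  stopifnot(inherits(params, "city_params"))
  nx <- params$grid_nx; ny <- params$grid_ny; s <- params$block_spacing
  if (nx < 2 || ny < 2) abort("The lattice needs at least 2 x 2 intersections.")
  if (s <= 0) abort("`block_spacing` must be positive.")
  xs <- (seq_len(nx) - 1) * s
  ys <- (seq_len(ny) - 1) * s
  horiz <- tidyr::expand_grid(i = seq_len(nx - 1), j = seq_len(ny)) |>
    dplyr::mutate(x0 = xs[.data$i], y0 = ys[.data$j],
                  x1 = xs[.data$i + 1L], y1 = ys[.data$j])
  vert <- tidyr::expand_grid(i = seq_len(nx), j = seq_len(ny - 1)) |>
    dplyr::mutate(x0 = xs[.data$i], y0 = ys[.data$j],
                  x1 = xs[.data$i], y1 = ys[.data$j + 1L])
  edges <- dplyr::bind_rows(horiz, vert) |>
    dplyr::select(!c("i", "j")) |>
    dplyr::mutate(
      length_m = sqrt((.data$x1 - .data$x0)^2 + (.data$y1 - .data$y0)^2),
      edge_id = sprintf("w%05d", dplyr::row_number()),
      .before = 1
    )
  edges[c("edge_id", "x0", "y0", "x1", "y1", "length_m")]
}

#' Multi-centre population raster
#'
#' Spreads each population centre's total over the raster with a Gaussian
#' kernel of the centre's decay length, normalised over the cells inside the
#' extent so that total mass is conserved exactly.
#'
#' @param params A [city_params()] object.
#' @return A `pop_raster` object (origin, cell size, matrix of person
#'   counts per cell).
#' @export
make_population_raster <- function(params) {
  stopifnot(inherits(params, "city_params"))
  ext <- params$extent
  cell <- params$raster_cell
  nx <- as.integer(round(extent_width(ext) / cell))
  ny <- as.integer(round(extent_height(ext) / cell))
  if (nx < 1 || ny < 1) abort("The raster must contain at least one cell.")
  cx <- ext[["xmin"]] + (seq_len(nx) - 0.5) * cell
  cy <- ext[["ymin"]] + (seq_len(ny) - 0.5) * cell
  centers <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  values <- numeric(nrow(centers))
  for (k in seq_len(nrow(params$pop_centers))) {
    pc <- params$pop_centers[k, ]
    d2 <- (centers$x - pc$x)^2 + (centers$y - pc$y)^2
    kern <- exp(-d2 / (2 * pc$decay^2))
    values <- values + pc$total * kern / sum(kern)
  }
  new_pop_raster(origin = c(ext[["xmin"]], ext[["ymin"]]),
                 cell_size = cell,
                 values = matrix(values, nrow = nx, ncol = ny))
}

new_pop_raster <- function(origin, cell_size, values) {
  structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         nx = nrow(values), ny = ncol(values), values = values),
    class = "pop_raster"
  )
}

#' @export
print.pop_raster <- function(x, ...) {
  cat(sprintf("<pop_raster> %d x %d cells of %g m, total %.1f persons\n",
              x$nx, x$ny, x$cell_size, sum(x$values)))
  invisible(x)
}

# Cell centres of a pop_raster as a tibble (x, y, pop).
raster_cells <- function(raster) {
  cx <- raster$origin[1] + (seq_len(raster$nx) - 0.5) * raster$cell_size
  cy <- raster$origin[2] + (seq_len(raster$ny) - 0.5) * raster$cell_size
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  tibble(x = g$x, y = g$y, pop = as.vector(raster$values))
}

#' @method tidy pop_raster
#' @export
tidy.pop_raster <- function(x, ...) raster_cells(x)

#' Sample a facility point pattern
#'
#' Generates `n` points in `extent` from one of three processes:
#' `"uniform"` (homogeneous Poisson conditioned on `n`, i.e. a binomial
#' process), `"thomas"` (uniform parents, Gaussian offspring; offsets
#' falling outside the extent are redrawn so exactly `n` points remain) or
#' `"lattice"` (a regular grid; for square `n` an exact
#' `sqrt(n) x sqrt(n)` grid).
#'
#' @param n Number of points (>= 2).
#' @param process One of `"uniform"`, `"thomas"`, `"lattice"`.
#' @param extent Extent rectangle.
#' @param parents Number of Thomas parent points.
#' @param cluster_sd Gaussian offspring standard deviation in metres
#'   (Thomas only).
#' @param class Optional class label attached as a column.
#' @param seed Optional integer seed; when given, sampling runs in a local
#'   RNG scope and is reproducible.
#' @return A tibble with columns `x`, `y` (and `class` if given).
#' @export
sample_facilities <- function(n, process = c("uniform", "thomas", "lattice"),
                              extent, parents = 5L, cluster_sd = NULL,
                              class = NULL, seed = NULL) {
  if (!is.character(process) || !all(process %in% c("uniform", "thomas", "lattice"))) {
    abort(sprintf("Unknown point process '%s'.", paste(process, collapse = ",")))
  }
  process <- match.arg(process)
  if (n < 2) abort("`n` must be at least 2.")
  extent <- as_extent(extent)
  draw <- function() {
    switch(process,
      uniform = tibble(
        x = runif(n, extent[["xmin"]], extent[["xmax"]]),
        y = runif(n, extent[["ymin"]], extent[["ymax"]])
      ),
      thomas = {
        if (is.null(cluster_sd) || is.na(cluster_sd) || cluster_sd <= 0) {
          abort("The Thomas process needs a positive `cluster_sd`.")
        }
        if (parents < 1) abort("The Thomas process needs at least one parent.")
        px <- runif(parents, extent[["xmin"]], extent[["xmax"]])
        py <- runif(parents, extent[["ymin"]], extent[["ymax"]])
        idx <- sample.int(parents, n, replace = TRUE)
        x <- px[idx] + rnorm(n, 0, cluster_sd)
        y <- py[idx] + rnorm(n, 0, cluster_sd)
        out <- x < extent[["xmin"]] | x > extent[["xmax"]] |
               y < extent[["ymin"]] | y > extent[["ymax"]]
        while (any(out)) {
          k <- sum(out)
          x[out] <- px[idx[out]] + rnorm(k, 0, cluster_sd)
          y[out] <- py[idx[out]] + rnorm(k, 0, cluster_sd)
          out <- x < extent[["xmin"]] | x > extent[["xmax"]] |
                 y < extent[["ymin"]] | y > extent[["ymax"]]
        }
        tibble(x = x, y = y)
      },
      lattice = {
        m <- round(sqrt(n))
        if (m * m == n) {
          gx <- m; gy <- m
        } else {
          gx <- as.integer(ceiling(sqrt(n)))
          gy <- as.integer(ceiling(n / gx))
        }
        g <- tidyr::expand_grid(j = seq_len(gy), i = seq_len(gx))
        g <- g[seq_len(n), ]
        tibble(
          x = extent[["xmin"]] + (g$i - 0.5) * extent_width(extent) / gx,
          y = extent[["ymin"]] + (g$j - 0.5) * extent_height(extent) / gy
        )
      }
    )
  }
  pts <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  if (!is.null(class)) pts$class <- class
  pts
}

#' Transit lines and stations on grid corridors
#'
#' Places each line's stations along its grid corridor (a row or column of
#' the street lattice) at the requested spacing, starting at the corridor's
#' origin, so a corridor of length `L` holds `floor(L / spacing) + 1`
#' stations ordered along the corridor.
#'
#' @param params A [city_params()] object.
#' @return A list with `lines` (tibble: `line_id`, `mode`, `n_stations`) and
#'   `stations` (tibble: `station_id`, `line_id`, `mode`, `seq`, `x`, `y`).
#' @export
make_transit <- function(params) {
  stopifnot(inherits(params, "city_params"))
  s <- params$block_spacing
  specs <- params$transit_specs
  stations <- purrr::pmap(specs, function(line_id, mode, axis, index,
                                          station_spacing, ...) {
    len <- if (axis == "row") extent_width(params$extent) else
      extent_height(params$extent)
    if (station_spacing > len) {
      abort(sprintf("Line '%s': station spacing %g m exceeds its %g m corridor.",
                    line_id, station_spacing, len))
    }
    n_st <- floor(len / station_spacing) + 1L
    along <- (seq_len(n_st) - 1) * station_spacing
    fixed <- (index - 1) * s
    tibble(
      station_id = sprintf("%s_s%02d", line_id, seq_len(n_st)),
      line_id = line_id, mode = mode, seq = seq_len(n_st),
      x = if (axis == "row") along else fixed,
      y = if (axis == "row") fixed else along
    )
  }) |> dplyr::bind_rows()
  lines <- stations |>
    dplyr::summarise(n_stations = dplyr::n(), .by = c("line_id", "mode"))
  list(lines = lines, stations = stations)
}

#' Voronoi district partition
#'
#' Draws `n_districts` seed points uniformly in the extent and returns their
#' Voronoi cells clipped to the extent. The cells are convex polygons that
#' tile the extent exactly; irregular district shapes exercise the
#' area-intersection code the way real administrative boundaries do.
#'
#' @param params A [city_params()] object.
#' @return A tibble with columns `district`, `seed_x`, `seed_y`, `geometry`
#'   (list of vertex matrices), `area_m2`.
#' @export
make_districts <- function(params) {
  stopifnot(inherits(params, "city_params"))
  k <- params$n_districts
  seeds <- tibble(
    x = runif(k, params$extent[["xmin"]], params$extent[["xmax"]]),
    y = runif(k, params$extent[["ymin"]], params$extent[["ymax"]])
  )
  cells <- voronoi_partition(seeds, params$extent)
  tibble(
    district = sprintf("district_%02d", seq_len(k)),
    seed_x = seeds$x, seed_y = seeds$y,
    geometry = cells,
    area_m2 = purrr::map_dbl(cells, polygon_area)
  )
}

# District membership: polygon containment (first match wins on shared
# boundaries), with nearest-seed fallback for points that slip through
# numerically. For a Voronoi partition the two rules agree.
district_of <- function(districts, x, y) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(districts))) {
    todo <- which(is.na(out))
    if (!length(todo)) break
    hit <- point_in_convex(districts$geometry[[i]], x[todo], y[todo])
    out[todo[hit]] <- districts$district[i]
  }
  miss <- which(is.na(out))
  if (length(miss)) {
    k <- nrow(districts)
    d2 <- matrix(0, nrow = length(miss), ncol = k)
    for (i in seq_len(k)) {
      d2[, i] <- (x[miss] - districts$seed_x[i])^2 +
                 (y[miss] - districts$seed_y[i])^2
    }
    out[miss] <- districts$district[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Generate a complete synthetic city
#'
#' Runs every generator stage under the parameter seed: walk network,
#' Voronoi districts, population raster, facility point patterns per class,
#' transit lines and stations. A fixed `city_params` object yields a
#' bit-identical city on every call.
#'
#' @param params A [city_params()] object.
#' @return A `synthetic_city` object: list with `params`, `extent`,
#'   `walk_edges`, `districts`, `population`, `facilities` (tibble with
#'   `x`, `y`, `class`), `transit_lines`, `stations`.
#' @export
synthetic_city <- function(params = city_params()) {
  stopifnot(inherits(params, "city_params"))
  withr::with_seed(params$seed, {
    walk_edges <- make_grid_walk_network(params)
    districts <- make_districts(params)
    population <- make_population_raster(params)
    facilities <- purrr::pmap(params$facility_specs,
      function(class, n, process, parents, cluster_sd, ...) {
        sample_facilities(n = n, process = process, extent = params$extent,
                          parents = parents, cluster_sd = cluster_sd,
                          class = class)
      }) |> dplyr::bind_rows()
    transit <- make_transit(params)
    structure(
      list(params = params, extent = params$extent,
           walk_edges = walk_edges, districts = districts,
           population = population, facilities = facilities,
           transit_lines = transit$lines, stations = transit$stations),
      class = "synthetic_city"
    )
  })
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city>\n")
  cat(sprintf("  %d walk edges | %d districts | %.0f persons\n",
              nrow(x$walk_edges), nrow(x$districts), sum(x$population$values)))
  cls <- dplyr::count(x$facilities, .data$class)
  cat(sprintf("  facilities: %s\n",
              paste(sprintf("%s=%d", cls$class, cls$n), collapse = ", ")))
  cat(sprintf("  transit: %d lines, %d stations | seed %d\n",
              nrow(x$transit_lines), nrow(x$stations), x$params$seed))
  invisible(x)
}

#' @method autoplot synthetic_city
#' @export
autoplot.synthetic_city <- function(object, ...) {
  dist_df <- tidyr::unnest(
    dplyr::mutate(object$districts,
                  xy = purrr::map(.data$geometry, ~ tibble(x = .x[, 1], y = .x[, 2]))),
    "xy"
  )
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = dist_df,
      ggplot2::aes(.data$x, .data$y, group = .data$district),
      fill = NA, colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_segment(
      data = object$walk_edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1),
      colour = "grey85", linewidth = 0.2
    ) +
    ggplot2::geom_point(
      data = object$stations,
      ggplot2::aes(.data$x, .data$y, shape = .data$mode),
      colour = "grey30", size = 1.5
    ) +
    ggplot2::geom_point(
      data = object$facilities,
      ggplot2::aes(.data$x, .data$y, colour = .data$class),
      size = 0.8
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  colour = "facility class", shape = "station mode") +
    ggplot2::theme_minimal()
}
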