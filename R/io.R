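# Plain-text geospatial readers/writers: GeoJSON for vectors, ESRI ASCII
# grid for rasters, CSV for tables. All geometries are planar metres in a
# local frame; the GeoJSON "coordinates" carry those metres directly.

gj_collection <- function(features, path) {
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}

row_properties <- function(df, i, drop) {
  cols <- setdiff(names(df), drop)
  props <- lapply(cols, function(cl) df[[cl]][i])
  setNames(props, cols)
}

#' Write points as a GeoJSON FeatureCollection
#'
#' Columns other than `x`, `y` become feature properties.
#'
#' @param points Data frame with columns `x`, `y`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_geojson_points <- function(points, path) {
  check_points(points, min_n = 1L)
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = row_properties(points, i, c("x", "y")))
  })
  gj_collection(features, path)
}

#' Read a GeoJSON point FeatureCollection
#'
#' @param path GeoJSON file with Point features.
#' @return A tibble with `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map(gj$features, function(f) {
    stopifnot(identical(f$geometry$type, "Point"))
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      lapply(f$properties, function(p) if (is.null(p)) NA else p))
  })
  dplyr::bind_rows(rows)
}

#' Write segments as GeoJSON LineStrings
#'
#' @param edges Data frame with columns `x0`, `y0`, `x1`, `y1`; other
#'   columns become properties.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_geojson_lines <- function(edges, path) {
  features <- lapply(seq_len(nrow(edges)), function(i) {
    coords <- list(c(edges$x0[i], edges$y0[i]), c(edges$x1[i], edges$y1[i]))
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = coords),
         properties = row_properties(edges, i, c("x0", "y0", "x1", "y1")))
  })
  gj_collection(features, path)
}

# Close a ring (first vertex repeated last); a matrix serialises as the
# GeoJSON nested coordinate array.
close_ring <- function(xy) {
  unname(rbind(xy, xy[1, , drop = FALSE]))
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' @param polygons Data frame with a `geometry` list column of `n x 2`
#'   vertex matrices; other columns (except internal seed columns) become
#'   properties.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path) {
  features <- lapply(seq_len(nrow(polygons)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(close_ring(polygons$geometry[[i]]))),
         properties = row_properties(polygons, i, "geometry"))
  })
  gj_collection(features, path)
}

#' Write a coverage region as a GeoJSON MultiPolygon feature
#'
#' One stadium polygon per buffered segment; overlapping parts overlap (the
#' region semantics live in [region_contains()]).
#'
#' @param coverage A `coverage` object.
#' @param path Output file.
#' @param properties Named list of feature properties.
#' @param n_arc Vertices per semicircular cap (see [coverage_outline()]).
#' @return The path, invisibly.
#' @export
write_geojson_coverage <- function(coverage, path, properties = list(),
                                   n_arc = 8L) {
  outlines <- lapply(coverage_outline(coverage, n_arc = n_arc),
                     function(p) round(p, 2))
  feature <- list(
    type = "Feature",
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(outlines, function(p) list(close_ring(p)))),
    properties = c(properties, list(buffer_width_m = coverage$width,
                                    n_segments = length(outlines)))
  )
  gj_collection(list(feature), path)
}

#' Read a point pattern from CSV
#'
#' Expects columns `x`, `y` and optionally `class`.
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_pattern_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  check_points(df, min_n = 1L)
  df
}

#' Write a population raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format: a 6-line header followed by rows of cell
#' values from the top row down.
#'
#' @param raster A `pop_raster`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "pop_raster"))
  header <- c(
    sprintf("ncols %d", raster$nx),
    sprintf("nrows %d", raster$ny),
    sprintf("xllcorner %.6f", raster$origin[1]),
    sprintf("yllcorner %.6f", raster$origin[2]),
    sprintf("cellsize %.6f", raster$cell_size),
    "NODATA_value -9999"
  )
  rows <- vapply(rev(seq_len(raster$ny)), function(j) {
    paste(formatC(raster$values[, j], format = "g", digits = 10), collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a population raster
#'
#' @param path `.asc` file.
#' @return A `pop_raster`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hd <- strsplit(trimws(lines[1:6]), "\\s+")
  vals <- setNames(vapply(hd, function(h) as.numeric(h[2]), numeric(1)),
                   tolower(vapply(hd, `[`, character(1), 1)))
  nx <- as.integer(vals[["ncols"]]); ny <- as.integer(vals[["nrows"]])
  body <- lapply(lines[7:(6 + ny)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- matrix(0, nrow = nx, ncol = ny)
  for (r in seq_len(ny)) m[, ny - r + 1L] <- body[[r]]
  m[m == vals[["nodata_value"]]] <- NA
  new_pop_raster(origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
                 cell_size = vals[["cellsize"]], values = m)
}

#' Write a multimodal graph as node and edge CSVs
#'
#' @param graph A `multimodal_graph`.
#' @param nodes_path,edges_path Output CSV files.
#' @return Invisibly, the two paths.
#' @export
write_graph_csv <- function(graph, nodes_path, edges_path) {
  readr::write_csv(graph$nodes, nodes_path)
  readr::write_csv(graph$edges[c("edge_id", "from", "to", "type",
                                 "length_m", "cost_s",
                                 "x0", "y0", "x1", "y1")], edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Reload a multimodal graph from node and edge CSVs
#'
#' @param nodes_path,edges_path CSV files written by [write_graph_csv()].
#' @param params A [network_params()] object to attach.
#' @return A `multimodal_graph` (without the station table).
#' @export
read_graph_csv <- function(nodes_path, edges_path, params = network_params()) {
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE)
  edges <- readr::read_csv(edges_path, show_col_types = FALSE)
  new_multimodal_graph(nodes, edges, stations = NULL, params = params)
}

# ---- Run configuration -------------------------------------------------

config_defaults <- function() {
  list(
    seed = 1L,
    mode = "synthetic",
    city = list(),
    paths = list(),
    network = list(v_walk = 1.2, v_bus_kmh = 40, v_rail_kmh = 70,
                   dwell_s = 30, snap_tolerance = 500),
    # buffer comparable to half the synthetic block spacing, so service
    # polygons fill the street blocks they reach (denser real networks
    # warrant narrower buffers)
    access = list(thresholds_min = c(15, 30, 60), buffer_width = 250),
    kde = list(radius = 1000, cell_size = 250)
  )
}

# YAML 1.1 reads the bare keys `y`/`n` as booleans; restore them (they are
# legitimate column names for coordinates and counts).
yaml_key_fix <- function(lst) {
  if (!is.list(lst)) return(lst)
  nm <- names(lst)
  if (!is.null(nm)) {
    nm[nm == "TRUE"] <- "y"
    nm[nm == "FALSE"] <- "n"
    names(lst) <- nm
  }
  lapply(lst, yaml_key_fix)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration and fills every missing field with
#' its default: walking 1.2 m/s, bus 40 km/h, rail 70 km/h, dwell 30 s,
#' thresholds 15/30/60 min. An empty file yields the full default
#' (synthetic-mode) configuration. All validation problems are collected
#' and reported together.
#'
#' @param path Path to a YAML/JSON file, or a named list of overrides.
#' @return A validated `run_config` object.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) {
    list()
  } else if (is.list(path)) {
    path
  } else {
    if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
    yaml_key_fix(yaml::read_yaml(path) %||% list())
  }
  defs <- config_defaults()
  problems <- character(0)
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  cfg <- defs
  for (k in intersect(names(user), names(defs))) {
    if (is.list(defs[[k]]) && !is.null(names(defs[[k]]))) {
      sub_unknown <- setdiff(names(user[[k]]), names(defs[[k]]))
      if (k %in% c("city", "paths")) sub_unknown <- character(0)
      if (length(sub_unknown)) {
        problems <- c(problems, sprintf("unknown key(s) in `%s`: %s", k,
                                        paste(sub_unknown, collapse = ", ")))
      }
      cfg[[k]] <- utils::modifyList(defs[[k]], user[[k]] %||% list())
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  if (length(cfg$paths) > 0 && length(cfg$city) > 0) {
    problems <- c(problems, "give either `paths` or `city` parameters, not both")
  }
  if (length(cfg$paths) > 0) cfg$mode <- "files"
  if (!cfg$mode %in% c("synthetic", "files")) {
    problems <- c(problems, "`mode` must be 'synthetic' or 'files'")
  }
  nw <- cfg$network
  if (any(unlist(nw[c("v_walk", "v_bus_kmh", "v_rail_kmh")]) <= 0)) {
    problems <- c(problems, "network speeds must be positive")
  }
  if (nw$dwell_s < 0) problems <- c(problems, "`dwell_s` must be non-negative")
  thr <- cfg$access$thresholds_min
  if (any(thr <= 0) || is.unsorted(thr, strictly = TRUE)) {
    problems <- c(problems, "`thresholds_min` must be strictly increasing and positive")
  }
  if (cfg$access$buffer_width <= 0) problems <- c(problems, "`buffer_width` must be positive")
  if (cfg$kde$radius <= 0 || cfg$kde$cell_size <= 0) {
    problems <- c(problems, "kde radius and cell_size must be positive")
  }
  if (length(problems)) {
    abort(c("Invalid configuration:", setNames(problems, rep("x", length(problems)))))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Stable hash of a run configuration
#'
#' @param config A `run_config` object.
#' @return A character hash; identical configurations hash identically.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> mode %s | seed %d | hash %s\n",
              x$mode, x$seed, config_hash(x)))
  cat(sprintf("  network: walk %.2f m/s, bus %g km/h, rail %g km/h, dwell %g s\n",
              x$network$v_walk, x$network$v_bus_kmh, x$network$v_rail_kmh,
              x$network$dwell_s))
  cat(sprintf("  access: %s min, buffer %g m | kde: r %g m, cell %g m\n",
              paste(x$access$thresholds_min, collapse = "/"),
              x$access$buffer_width, x$kde$radius, x$kde$cell_size))
  invisible(x)
}
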