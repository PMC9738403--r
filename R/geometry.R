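# Minimal planar geometry used across the package. All coordinates are
# planar metres in a local projected frame; no geographic lat/lon.

#' Validate a rectangular extent
#'
#' An extent is a numeric vector `c(xmin, ymin, xmax, ymax)` in metres.
#'
#' @param extent Numeric vector of length 4: `c(xmin, ymin, xmax, ymax)`.
#' @return The validated extent, with names attached.
#' @export
as_extent <- function(extent) {
  extent <- as.numeric(extent)
  if (length(extent) != 4 || anyNA(extent) || !all(is.finite(extent))) {
    abort("`extent` must be a finite numeric vector c(xmin, ymin, xmax, ymax).")
  }
  if (extent[3] <= extent[1] || extent[4] <= extent[2]) {
    abort("`extent` must satisfy xmax > xmin and ymax > ymin.")
  }
  setNames(extent, c("xmin", "ymin", "xmax", "ymax"))
}

extent_width <- function(extent) extent[[3]] - extent[[1]]
extent_height <- function(extent) extent[[4]] - extent[[2]]
extent_area <- function(extent) extent_width(extent) * extent_height(extent)

# Distance from points (px, py) to the segment (x0,y0)-(x1,y1); vectorised
# over the points.
dist_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return(sqrt((px - x0)^2 + (py - y0)^2))
  }
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# Signed shoelace area of a polygon given as an n x 2 matrix (not closed).
polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a simple polygon
#'
#' @param xy An `n x 2` matrix of vertices (not closed).
#' @return Area in square metres.
#' @export
polygon_area <- function(xy) abs(polygon_area_signed(xy))

# Clip a convex polygon by the half-plane a*x + b*y <= cc (Sutherland-Hodgman
# against a single edge). Returns a matrix, possibly with 0 rows.
clip_halfplane <- function(poly, a, b, cc, eps = 1e-9) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(matrix(numeric(0), ncol = 2))
  d <- a * poly[, 1] + b * poly[, 2] - cc
  scale <- max(abs(d), 1)
  keep <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= eps * scale) keep[[length(keep) + 1L]] <- poly[i, ]
    if ((di < -eps * scale && dj > eps * scale) ||
        (di > eps * scale && dj < -eps * scale)) {
      t <- di / (di - dj)
      keep[[length(keep) + 1L]] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (length(keep) == 0) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, keep)
}

# Ensure counter-clockwise orientation.
polygon_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

# Vectorised point-in-convex-polygon test (boundary counts as inside).
point_in_convex <- function(poly, x, y, eps = 1e-9) {
  poly <- polygon_ccw(poly)
  n <- nrow(poly)
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]
    ey <- poly[j, 2] - poly[i, 2]
    cross <- ex * (y - poly[i, 2]) - ey * (x - poly[i, 1])
    inside <- inside & (cross >= -eps * (abs(ex) + abs(ey) + 1))
  }
  inside
}

#' Voronoi partition of a rectangular extent
#'
#' Computes the Voronoi cell of every seed point, clipped to `extent`, by
#' half-plane intersection (each cell is the rectangle cut by the
#' perpendicular bisectors against every other seed). Cells are convex and
#' tile the extent exactly.
#'
#' @param seeds A data frame with columns `x`, `y` (one seed per row).
#' @param extent Extent rectangle, see [as_extent()].
#' @return A list of `n x 2` vertex matrices, one per seed, in seed order.
#' @export
voronoi_partition <- function(seeds, extent) {
  extent <- as_extent(extent)
  sx <- seeds$x; sy <- seeds$y
  k <- length(sx)
  if (k < 1) abort("At least one seed point is required.")
  rect <- matrix(c(
    extent[["xmin"]], extent[["ymin"]],
    extent[["xmax"]], extent[["ymin"]],
    extent[["xmax"]], extent[["ymax"]],
    extent[["xmin"]], extent[["ymax"]]
  ), ncol = 2, byrow = TRUE)
  lapply(seq_len(k), function(i) {
    poly <- rect
    for (j in seq_len(k)) {
      if (j == i) next
      # closer to seed i than to seed j: 2(xj-xi) x + 2(yj-yi) y <= |sj|^2-|si|^2
      a <- 2 * (sx[j] - sx[i])
      b <- 2 * (sy[j] - sy[i])
      cc <- sx[j]^2 + sy[j]^2 - sx[i]^2 - sy[i]^2
      poly <- clip_halfplane(poly, a, b, cc)
      if (nrow(poly) == 0) break
    }
    polygon_ccw(poly)
  })
}

# ---- Regions -----------------------------------------------------------
# A region is any object with a region_contains() method; areas are measured
# by cell-centre quadrature so that all area/population ratios in the
# package share one inclusion rule.

#' Test whether points fall inside a region
#'
#' Generic membership test used by the service-area ratios. Methods exist
#' for buffer coverages ([coverage_polygon()]), convex polygons
#' ([region_polygon()]) and half-planes ([region_halfspace()]).
#'
#' @param region A region object.
#' @param x,y Numeric coordinate vectors (metres).
#' @return Logical vector, one element per point.
#' @export
region_contains <- function(region, x, y) UseMethod("region_contains")

#' @export
region_contains.default <- function(region, x, y) {
  abort(paste0("No region_contains() method for class <",
               paste(class(region), collapse = "/"), ">."))
}

#' Half-plane region
#'
#' The set of points with `a*x + b*y <= c`. Mostly useful for exercising the
#' area-ratio machinery against closed forms.
#'
#' @param a,b,c Coefficients of the inequality `a*x + b*y <= c`.
#' @return A region object.
#' @export
region_halfspace <- function(a, b, c) {
  structure(list(a = a, b = b, c = c), class = "region_halfspace")
}

#' @export
region_contains.region_halfspace <- function(region, x, y) {
  region$a * x + region$b * y <= region$c
}

#' Convex polygon region
#'
#' @param xy An `n x 2` vertex matrix of a convex polygon.
#' @return A region object.
#' @export
region_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) abort("A polygon region needs at least 3 vertices.")
  structure(list(xy = polygon_ccw(xy)), class = "region_polygon")
}

#' @export
region_contains.region_polygon <- function(region, x, y) {
  point_in_convex(region$xy, x, y)
}

#' Region area by cell-centre quadrature
#'
#' Approximates the area of `region` intersected with `extent` by laying a
#' regular grid over the extent and counting cells whose centres fall inside
#' the region. The same cell-centre rule underlies [sar()] and [spr()].
#'
#' @param region A region object.
#' @param extent Bounding rectangle for the quadrature.
#' @param cell_size Target quadrature cell size in metres (the actual cell
#'   is adjusted so cells tile the extent exactly).
#' @return Estimated area in square metres.
#' @export
region_area <- function(region, extent, cell_size) {
  extent <- as_extent(extent)
  if (!is.numeric(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a positive number of metres.")
  }
  nx <- max(1L, as.integer(ceiling(extent_width(extent) / cell_size)))
  ny <- max(1L, as.integer(ceiling(extent_height(extent) / cell_size)))
  csx <- extent_width(extent) / nx
  csy <- extent_height(extent) / ny
  cx <- extent[["xmin"]] + (seq_len(nx) - 0.5) * csx
  cy <- extent[["ymin"]] + (seq_len(ny) - 0.5) * csy
  pts <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  sum(region_contains(region, pts$x, pts$y)) * csx * csy
}

# Axis-aligned bounding box of a polygon / segment set, as an extent.
bbox_extent <- function(x, y, pad = 0) {
  as_extent(c(min(x) - pad, min(y) - pad, max(x) + pad, max(y) + pad))
}
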