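# Point-pattern statistics for facility layouts: Clark-Evans
# nearest-neighbour ratio, quartic kernel density, mean centre, and
# standard deviational ellipse. Patterns are plain data frames with `x` and
# `y` columns in metres (optionally a `class` label); statistics are
# computed without edge correction.

check_points <- function(points, min_n = 1L, what = "points") {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    abort(sprintf("`%s` must be a data frame with columns `x` and `y`.", what))
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    abort(sprintf("`%s` coordinates must be finite.", what))
  }
  if (nrow(points) < min_n) {
    abort(sprintf("`%s` needs at least %d points (got %d).",
                  what, min_n, nrow(points)))
  }
  invisible(points)
}

#' Nearest-neighbour distance of every point
#'
#' Distance from each point to its closest other point, computed with a
#' uniform-grid spatial index (expanding ring search), so typical patterns
#' are handled in near-linear time. Coincident duplicate points contribute
#' a distance of zero with a warning.
#'
#' @param points Data frame with columns `x`, `y` (metres), at least 2 rows.
#' @return Numeric vector of distances, one per point.
#' @export
nearest_neighbor_distances <- function(points) {
  check_points(points, min_n = 2L)
  x <- points$x
  y <- points$y
  n <- length(x)
  xr <- range(x); yr <- range(y)
  span <- max(xr[2] - xr[1], yr[2] - yr[1])
  if (span == 0) {
    warn("All points are coincident; nearest-neighbour distances are 0.")
    return(numeric(n))
  }
  m <- max(1L, as.integer(floor(sqrt(n))))
  cs <- span / m
  mx <- as.integer(floor((xr[2] - xr[1]) / cs)) + 1L
  my <- as.integer(floor((yr[2] - yr[1]) / cs)) + 1L
  ix <- pmin(mx, 1L + as.integer(floor((x - xr[1]) / cs)))
  iy <- pmin(my, 1L + as.integer(floor((y - yr[1]) / cs)))
  lin <- (ix - 1L) * my + iy
  buckets <- split(seq_len(n), lin)
  get_bucket <- function(cx, cy) {
    if (cx < 1L || cx > mx || cy < 1L || cy > my) return(integer(0))
    buckets[[as.character((cx - 1L) * my + cy)]] %||% integer(0)
  }
  d <- numeric(n)
  kmax <- max(mx, my)
  for (p in seq_len(n)) {
    best <- Inf
    cx <- ix[p]; cy <- iy[p]
    k <- 0L
    repeat {
      cand <- if (k == 0L) {
        get_bucket(cx, cy)
      } else {
        ring <- list()
        for (dx in (-k):k) {
          if (abs(dx) == k) {
            for (dy in (-k):k) ring[[length(ring) + 1L]] <- get_bucket(cx + dx, cy + dy)
          } else {
            ring[[length(ring) + 1L]] <- get_bucket(cx + dx, cy - k)
            ring[[length(ring) + 1L]] <- get_bucket(cx + dx, cy + k)
          }
        }
        unlist(ring)
      }
      cand <- cand[cand != p]
      if (length(cand)) {
        best <- min(best, sqrt((x[cand] - x[p])^2 + (y[cand] - y[p])^2))
      }
      if (best <= k * cs || k > kmax) break
      k <- k + 1L
    }
    d[p] <- best
  }
  if (any(d == 0)) {
    warn("Coincident duplicate points found; zero distances contribute.")
  }
  d
}

#' Mean observed nearest-neighbour distance
#'
#' The average over all points of the distance to the nearest other point
#' (the observed numerator of the nearest-neighbour ratio).
#'
#' @inheritParams nearest_neighbor_distances
#' @return Mean nearest-neighbour distance in metres.
#' @export
mean_nn_distance <- function(points) {
  mean(nearest_neighbor_distances(points))
}

#' Expected nearest-neighbour distance under complete spatial randomness
#'
#' For a homogeneous Poisson process of `n` points in area `A` the expected
#' nearest-neighbour distance is `0.5 * sqrt(A / n)`.
#'
#' @param n Number of points.
#' @param area Study-area size in square metres.
#' @return Expected distance in metres.
#' @export
expected_nn_distance <- function(n, area) {
  if (!is.numeric(n) || any(n < 1)) abort("`n` must be >= 1.")
  if (!is.numeric(area) || any(area <= 0)) abort("`area` must be positive.")
  0.5 * sqrt(area / n)
}

#' Nearest-neighbour ratio and spatial-structure classification
#'
#' `R = r1bar / rebar`: the observed mean nearest-neighbour distance over
#' its expectation under complete spatial randomness. `R < 1` indicates an
#' aggregated (clustered) pattern, `R > 1` a uniform (dispersed) one, and
#' `R = 1` spatial randomness; a tolerance band around 1 decides the label
#' on finite data.
#'
#' @param r1bar Observed mean nearest-neighbour distance(s), metres.
#' @param rebar Expected distance(s) under randomness, metres.
#' @param tolerance Half-width of the "random" band around `R = 1`.
#' @return A tibble with columns `r1bar`, `rebar`, `R`, `classification`
#'   (one row per input pair).
#' @export
nn_ratio <- function(r1bar, rebar, tolerance = 0.01) {
  if (!is.numeric(rebar) || any(rebar <= 0)) abort("`rebar` must be positive.")
  if (!is.numeric(r1bar) || any(r1bar < 0)) abort("`r1bar` must be non-negative.")
  R <- r1bar / rebar
  classification <- dplyr::case_when(
    R < 1 - tolerance ~ "aggregation",
    R > 1 + tolerance ~ "uniform",
    .default = "random"
  )
  tibble(r1bar = r1bar, rebar = rebar, R = R, classification = classification)
}

#' Nearest-neighbour analysis of a point pattern
#'
#' Composes [mean_nn_distance()], [expected_nn_distance()] and [nn_ratio()]
#' for one pattern in a study area of size `area`. No edge correction is
#' applied, matching the plain Clark-Evans form.
#'
#' @inheritParams nearest_neighbor_distances
#' @param area Study-area size in square metres.
#' @param tolerance Classification tolerance, see [nn_ratio()].
#' @return An `nn_result` object with fields `n`, `area`, `r1bar`, `rebar`,
#'   `R` and `classification`; see [tidy.nn_result()].
#' @export
nn_analysis <- function(points, area, tolerance = 0.01) {
  check_points(points, min_n = 2L)
  if (!is.numeric(area) || length(area) != 1 || area <= 0) {
    abort("`area` must be a single positive number (square metres).")
  }
  r1bar <- mean_nn_distance(points)
  rebar <- expected_nn_distance(nrow(points), area)
  ratio <- nn_ratio(r1bar, rebar, tolerance)
  structure(
    list(n = nrow(points), area = area, r1bar = r1bar, rebar = rebar,
         R = ratio$R, classification = ratio$classification,
         tolerance = tolerance),
    class = "nn_result"
  )
}

#' @export
print.nn_result <- function(x, ...) {
  cat(sprintf(
    "<nn_result> n = %d, A = %.4g m^2\n  r1bar = %.2f m, rebar = %.2f m, R = %.3f (%s)\n",
    x$n, x$area, x$r1bar, x$rebar, x$R, x$classification))
  invisible(x)
}

#' Tidy a nearest-neighbour analysis
#'
#' @param x An `nn_result` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `area_m2`, `r1bar`, `rebar`, `R`,
#'   `classification`.
#' @method tidy nn_result
#' @export
tidy.nn_result <- function(x, ...) {
  tibble(n = x$n, area_m2 = x$area, r1bar = x$r1bar, rebar = x$rebar,
         R = x$R, classification = x$classification)
}

#' @rdname tidy.nn_result
#' @method glance nn_result
#' @export
glance.nn_result <- function(x, ...) tidy(x)

#' Quartic kernel density surface
#'
#' Evaluates at every grid-cell centre the sum over points of the quartic
#' (biweight) kernel `3 * (1 - (d/r)^2)^2 / (pi * r^2)` for `d < r`, giving
#' a density in points per square metre. Each point's kernel integrates to
#' one over its disc of radius `r`, so the surface mass of a pattern well
#' inside the extent equals the number of points.
#'
#' @inheritParams nearest_neighbor_distances
#' @param radius Kernel search radius `r` in metres.
#' @param cell_size Output grid cell size in metres.
#' @param extent Extent rectangle covered by the grid.
#' @return A `kde_grid` object; see [tidy.kde_grid()].
#' @export
kernel_density <- function(points, radius, cell_size, extent) {
  check_points(points, min_n = 1L)
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be positive.")
  if (!is.numeric(cell_size) || cell_size <= 0) abort("`cell_size` must be positive.")
  if (radius <= cell_size) {
    warn("Kernel radius is not larger than the cell size; the surface is undersampled.")
  }
  extent <- as_extent(extent)
  nx <- as.integer(ceiling(extent_width(extent) / cell_size))
  ny <- as.integer(ceiling(extent_height(extent) / cell_size))
  cx <- extent[["xmin"]] + (seq_len(nx) - 0.5) * cell_size
  cy <- extent[["ymin"]] + (seq_len(ny) - 0.5) * cell_size
  values <- matrix(0, nrow = nx, ncol = ny)
  norm <- 3 / (pi * radius^2)
  for (p in seq_len(nrow(points))) {
    px <- points$x[p]; py <- points$y[p]
    i <- which(abs(cx - px) < radius)
    j <- which(abs(cy - py) < radius)
    if (!length(i) || !length(j)) next
    d2 <- outer((cx[i] - px)^2, (cy[j] - py)^2, `+`)
    u2 <- d2 / radius^2
    k <- ifelse(u2 < 1, norm * (1 - u2)^2, 0)
    values[i, j] <- values[i, j] + k
  }
  structure(
    list(origin = c(extent[["xmin"]], extent[["ymin"]]),
         cell_size = cell_size, nx = nx, ny = ny,
         values = values, radius = radius, n = nrow(points)),
    class = "kde_grid"
  )
}

#' @export
print.kde_grid <- function(x, ...) {
  cat(sprintf(
    "<kde_grid> %d x %d cells of %g m, r = %g m, surface mass %.3f (n = %d)\n",
    x$nx, x$ny, x$cell_size, x$radius,
    sum(x$values) * x$cell_size^2, x$n))
  invisible(x)
}

#' Tidy a kernel density grid
#'
#' @param x A `kde_grid` object.
#' @param ... Unused.
#' @return A tibble with cell-centre coordinates `x`, `y` and `density`
#'   (points per square metre).
#' @method tidy kde_grid
#' @export
tidy.kde_grid <- function(x, ...) {
  cx <- x$origin[1] + (seq_len(x$nx) - 0.5) * x$cell_size
  cy <- x$origin[2] + (seq_len(x$ny) - 0.5) * x$cell_size
  g <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)
  vals <- as.vector(x$values)
  tibble(x = g$x, y = g$y, density = vals)
}

#' @method autoplot kde_grid
#' @export
autoplot.kde_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(density ~ (m^-2))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Mean centre of a point pattern
#'
#' The arithmetic mean of the `x` and `y` coordinates: the geographic
#' centre of gravity of the pattern.
#'
#' @inheritParams nearest_neighbor_distances
#' @return A one-row tibble with columns `x`, `y`.
#' @export
mean_center <- function(points) {
  check_points(points, min_n = 1L)
  tibble(x = mean(points$x), y = mean(points$y))
}

#' Standard deviational ellipse
#'
#' Summarises the directional spread of a pattern by the eigenstructure of
#' the coordinate covariance matrix `C` about the mean centre, using the
#' population (`1/n`) normalisation by default. The ellipse axes are the
#' square roots of the eigenvalues of `C` (one standard deviation; no
#' cartographic scaling constant is applied) and the rotation is the angle
#' of the dominant eigenvector, reported counter-clockwise from east in
#' `[0, pi)`. A collinear pattern yields `sigma_minor = 0` with a
#' degeneracy flag rather than an error; a perfectly isotropic pattern has
#' an arbitrary axis direction, reported as 0.
#'
#' @inheritParams nearest_neighbor_distances
#' @param ddof Delta degrees of freedom in the covariance denominator
#'   `n - ddof`; 0 (default) reproduces the population form, 1 the sample
#'   form.
#' @return A `deviational_ellipse` object with fields `center`,
#'   `sigma_major`, `sigma_minor`, `rotation`, `covariance`, `degenerate`;
#'   see [tidy.deviational_ellipse()].
#' @export
standard_deviational_ellipse <- function(points, ddof = 0) {
  check_points(points, min_n = 3L)
  n <- nrow(points)
  if (!ddof %in% c(0, 1)) abort("`ddof` must be 0 or 1.")
  mx <- mean(points$x); my <- mean(points$y)
  xt <- points$x - mx; yt <- points$y - my
  denom <- n - ddof
  C <- matrix(c(sum(xt^2), sum(xt * yt), sum(xt * yt), sum(yt^2)) / denom,
              nrow = 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  sigma_major <- sqrt(ev[1])
  sigma_minor <- sqrt(ev[2])
  tol <- 1e-12 * max(ev[1], 1)
  rotation <- if (ev[1] - ev[2] <= tol) {
    0
  } else {
    v <- eig$vectors[, 1]
    ang <- atan2(v[2], v[1]) %% pi
    if (ang >= pi) 0 else ang
  }
  structure(
    list(center = c(x = mx, y = my),
         sigma_major = sigma_major, sigma_minor = sigma_minor,
         rotation = rotation, covariance = C,
         degenerate = sigma_minor <= sqrt(tol),
         n = n, ddof = ddof),
    class = "deviational_ellipse"
  )
}

#' @export
print.deviational_ellipse <- function(x, ...) {
  cat(sprintf(
    "<deviational_ellipse> centre (%.1f, %.1f) m\n  sigma = (%.2f, %.2f) m, rotation %.1f deg%s\n",
    x$center[["x"]], x$center[["y"]], x$sigma_major, x$sigma_minor,
    x$rotation * 180 / pi, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tidy a standard deviational ellipse
#'
#' @param x A `deviational_ellipse` object.
#' @param ... Unused.
#' @return A one-row tibble with `center_x`, `center_y`, `sigma_major`,
#'   `sigma_minor`, `rotation_rad`, `degenerate`, `n`.
#' @method tidy deviational_ellipse
#' @export
tidy.deviational_ellipse <- function(x, ...) {
  tibble(center_x = x$center[["x"]], center_y = x$center[["y"]],
         sigma_major = x$sigma_major, sigma_minor = x$sigma_minor,
         rotation_rad = x$rotation, degenerate = x$degenerate, n = x$n)
}

# Ellipse outline as a tibble of vertices (for plotting / GeoJSON export).
ellipse_outline <- function(ellipse, n_vertices = 90L) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ca <- cos(ellipse$rotation); sa <- sin(ellipse$rotation)
  ex <- ellipse$sigma_major * cos(t)
  ey <- ellipse$sigma_minor * sin(t)
  tibble(
    x = ellipse$center[["x"]] + ca * ex - sa * ey,
    y = ellipse$center[["y"]] + sa * ex + ca * ey
  )
}

#' @method autoplot deviational_ellipse
#' @export
autoplot.deviational_ellipse <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points, ggplot2::aes(.data$x, .data$y),
      colour = "grey40", size = 0.8
    )
  }
  p +
    ggplot2::geom_path(
      data = ellipse_outline(object),
      ggplot2::aes(.data$x, .data$y), colour = "firebrick"
    ) +
    ggplot2::annotate("point", x = object$center[["x"]],
                      y = object$center[["y"]], shape = 3, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
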