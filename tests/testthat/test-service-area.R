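test_that("facilities snap to the walk network with walking initial cost", {
  coords <- rbind(c(0, 0), c(500, 0))
  tg <- toy_walk_graph(coords, 1, 2, 500)
  fac <- data.frame(x = c(0, 60), y = c(0, 0))
  src <- facility_sources(fac, tg$graph)
  expect_equal(src$init_cost_s, c(0, 50))     # 0 m and 60 m at 1.2 m/s
  expect_equal(nrow(src), 2)
  expect_equal(attr(src, "excluded"), 0L)

  far <- data.frame(x = c(0, 9e4), y = 0)
  expect_warning(src2 <- facility_sources(far, tg$graph), "excluded")
  expect_equal(nrow(src2), 1)
  expect_equal(attr(src2, "excluded"), 1L)
})

test_that("reach limit cases: tiny budgets and saturation", {
  coords <- rbind(c(0, 0), c(100, 0), c(100, 100))
  tg <- toy_walk_graph(coords, c(1, 2), c(2, 3), c(100, 100))
  g <- tg$graph
  eps <- multi_source_reach(g, tg$id[1], budget_s = 1e-3)
  expect_equal(sum(eps$node_cost$reached), 1)     # only the source node
  expect_true(all(eps$edges$covered_frac < 0.001))
  sat <- multi_source_reach(g, tg$id[1], budget_s = sum(g$edges$cost_s) + 1)
  expect_true(all(sat$edges$covered_frac == 1))
  expect_error(multi_source_reach(g, tg$id[1], budget_s = 0), "positive")
  expect_error(multi_source_reach(g, integer(0), 10), "non-empty")
})

test_that("multi-source reach matches exhaustive path enumeration", {
  withr::local_seed(101)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    spec <- random_small_graph(n, n_extra = 3L)
    tg <- toy_walk_graph(spec$coords, spec$from, spec$to, spec$lengths)
    n_src <- sample(1:2, 1)
    src_idx <- sample(n, n_src)
    init <- runif(n_src, 0, 60)
    budget <- runif(1, 50, 600)
    rc <- multi_source_reach(
      tg$graph,
      tibble::tibble(node = tg$id[src_idx], init_cost_s = init),
      budget_s = budget
    )
    oracle <- bf_min_costs(n, spec$from, spec$to, spec$lengths / 1.2,
                           sources = src_idx, init = init)
    got <- rc$node_cost$cost_s[match(tg$id, rc$node_cost$node)]
    expect_equal(got, oracle, tolerance = 1e-9)
    expect_equal(rc$node_cost$reached[match(tg$id, rc$node_cost$node)],
                 oracle <= budget)
  }
})

test_that("a buffered segment has the stadium area", {
  w <- 50; L <- 400
  cov <- coverage_polygon(tibble::tibble(x0 = 100, y0 = 300, x1 = 100 + L,
                                         y1 = 300), buffer_width = w)
  got <- region_area(cov, c(0, 0, 600, 600), cell_size = 2)
  expect_equal(got, 2 * w * L + pi * w^2, tolerance = 0.01)

  # empty reach: empty region, zero area
  empty <- coverage_polygon(tibble::tibble(x0 = numeric(0), y0 = numeric(0),
                                           x1 = numeric(0), y1 = numeric(0)))
  expect_equal(region_area(empty, c(0, 0, 600, 600), cell_size = 5), 0)

  # two disjoint components: areas add
  two <- coverage_polygon(tibble::tibble(x0 = c(100, 100), y0 = c(100, 500),
                                         x1 = c(300, 300), y1 = c(100, 500)),
                          buffer_width = 20)
  expect_equal(region_area(two, c(0, 0, 600, 600), cell_size = 1),
               2 * (2 * 20 * 200 + pi * 20^2), tolerance = 0.01)
})

test_that("coverage membership agrees with direct distance checks", {
  withr::local_seed(44)
  segs <- tibble::tibble(x0 = runif(5, 0, 500), y0 = runif(5, 0, 500),
                         x1 = runif(5, 0, 500), y1 = runif(5, 0, 500))
  cov <- coverage_polygon(segs, buffer_width = 40)
  x <- runif(300, 0, 500); y <- runif(300, 0, 500)
  want <- rep(FALSE, 300)
  for (i in 1:5) {
    want <- want | medaccess:::dist_point_segment(
      x, y, segs$x0[i], segs$y0[i], segs$x1[i], segs$y1[i]) <= 40
  }
  expect_equal(region_contains(cov, x, y), want)
})

test_that("SAR handles containment, disjointness and a half-plane clip", {
  district <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2, byrow = TRUE)
  everything <- region_halfspace(0, 0, 1)     # 0 <= 1: the whole plane
  expect_equal(sar(everything, district, cell_size = 10), 1)
  nothing <- region_halfspace(0, 0, -1)
  expect_equal(sar(nothing, district, cell_size = 10), 0)
  half <- region_halfspace(1, 0, 50)
  expect_equal(sar(half, district, cell_size = 10), 0.5)
  expect_error(sar(half, matrix(c(0, 0, 1, 1, 2, 2), ncol = 2, byrow = TRUE),
                   cell_size = 10), "Degenerate")
})

test_that("SPR counts raster population by cell centres", {
  vals <- matrix(1, nrow = 10, ncol = 10)
  uni <- medaccess:::new_pop_raster(c(0, 0), 10, vals)
  district <- matrix(c(0, 0, 100, 0, 100, 100, 0, 100), ncol = 2, byrow = TRUE)
  expect_equal(spr(region_halfspace(1, 0, 50), uni, district), 0.5)
  expect_equal(spr(region_halfspace(0, 0, -1), uni, district), 0)

  # random raster against an independent ray-casting containment scan
  withr::local_seed(9)
  vals2 <- matrix(runif(100, 0, 50), nrow = 10)
  rnd <- medaccess:::new_pop_raster(c(0, 0), 10, vals2)
  poly <- matrix(c(12, 8, 95, 30, 60, 94), ncol = 2, byrow = TRUE)
  got <- spr(region_polygon(poly), rnd, district)
  cells <- tidy(rnd)
  inside <- ray_cast_inside(poly, cells$x, cells$y)
  expect_equal(got, sum(cells$pop[inside]) / sum(cells$pop), tolerance = 1e-12)

  # a district with no population reports NA, not 0
  zero <- medaccess:::new_pop_raster(c(0, 0), 10, matrix(0, 10, 10))
  expect_message(na <- spr(region_halfspace(0, 0, 1), zero, district),
                 "undefined")
  expect_true(is.na(na))
})

test_that("district accessibility is monotone in threshold and conserved", {
  city <- synthetic_city(small_city_params())
  g <- build_multimodal_graph(city)
  acc <- run_accessibility(city, g,
                           access_config(thresholds_min = c(5, 10, 20),
                                         buffer_width = 200))
  rec <- tidy(acc)
  expect_true(all(rec$SAR >= 0 & rec$SAR <= 1))
  expect_true(all(rec$SPR >= 0 & rec$SPR <= 1, na.rm = TRUE))
  mono <- rec |>
    dplyr::arrange(district, class, threshold_min) |>
    dplyr::summarise(ok = !is.unsorted(SAR) && !is.unsorted(SPR),
                     .by = c(district, class))
  expect_true(all(mono$ok))
  # sum of served population never exceeds the raster total
  served <- rec |>
    dplyr::summarise(sp = sum(sp), .by = c(class, threshold_min))
  expect_true(all(served$sp <= sum(city$population$values) + 1e-6))
  # averages are arithmetic means of the per-class ratios
  d1 <- acc$by_district[acc$by_district$threshold_min == 5, ]
  manual <- rec |>
    dplyr::filter(threshold_min == 5) |>
    dplyr::summarise(SAR = mean(SAR), .by = district)
  expect_equal(d1$SAR[match(manual$district, d1$district)], manual$SAR)
})

test_that("adding a transit line never shrinks reach", {
  city <- synthetic_city(small_city_params())
  walk_only <- build_walk_graph(city$walk_edges)
  full <- build_multimodal_graph(city)
  fac <- city$facilities[city$facilities$class == "clinic", ]
  src_w <- facility_sources(fac, walk_only)
  src_f <- facility_sources(fac, full)
  for (budget in c(300, 900)) {
    rw <- multi_source_reach(walk_only, src_w, budget)
    rf <- multi_source_reach(full, src_f, budget)
    walk_nodes <- walk_only$nodes$node
    cw <- rw$node_cost$cost_s[match(walk_nodes, rw$node_cost$node)]
    cf <- rf$node_cost$cost_s[match(walk_nodes, rf$node_cost$node)]
    expect_true(all(cf <= cw + 1e-9))
  }
})

test_that("a facility cluster lifts its own district's short-range access", {
  # all clinics in the south-west corner; districts split the square
  p <- city_params(
    seed = 5, grid_nx = 9, grid_ny = 9, block_spacing = 400,
    n_districts = 4, raster_cell = 200,
    pop_centers = data.frame(x = 1600, y = 1600, total = 1e5, decay = 1200),
    facility_specs = data.frame(class = "clinic", n = 8L, process = "thomas",
                                parents = 1L, cluster_sd = 150),
    transit_specs = data.frame(line_id = "b1", mode = "bus", axis = "row",
                               index = 5L, station_spacing = 400)
  )
  city <- synthetic_city(p)
  g <- build_multimodal_graph(city)
  acc <- run_accessibility(city, g,
                           access_config(thresholds_min = c(5, 10),
                                         buffer_width = 200))
  rec <- tidy(acc)
  home <- names(which.max(table(
    medaccess:::district_of(city$districts, city$facilities$x,
                            city$facilities$y))))
  ctr <- mean_center(city$facilities)
  d2 <- (city$districts$seed_x - ctr$x)^2 + (city$districts$seed_y - ctr$y)^2
  remote <- city$districts$district[which.max(d2)]
  r5 <- rec[rec$threshold_min == 5, ]
  expect_gt(r5$SPR[r5$district == home], r5$SPR[r5$district == remote])
})
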