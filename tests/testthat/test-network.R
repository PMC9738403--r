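test_that("walk edges cost their length at walking speed", {
  coords <- rbind(c(0, 0), c(120, 0), c(120, 1))
  tg <- toy_walk_graph(coords, from = c(1, 2), to = c(2, 3),
                       lengths = c(120, 1))
  e <- tg$graph$edges
  expect_equal(e$cost_s[e$length_m == 120], 100)
  expect_equal(e$cost_s[e$length_m == 1], 1 / 1.2)
})

test_that("zero-length walk edges are rejected and reported", {
  edges <- tibble::tibble(
    edge_id = c("ok", "bad"),
    x0 = c(0, 5), y0 = 0, x1 = c(10, 5), y1 = 0, length_m = c(10, 0)
  )
  expect_message(g <- build_walk_graph(edges), "bad")
  expect_equal(nrow(g$edges), 1)
})

test_that("near-coincident endpoints merge into one node", {
  edges <- tibble::tibble(
    x0 = c(0, 100.004), y0 = c(0, 0), x1 = c(100, 200), y1 = c(0, 0),
    length_m = c(100, 100)
  )
  g <- build_walk_graph(edges)
  expect_equal(nrow(g$nodes), 3)
})

test_that("station access links walk the snap distance", {
  coords <- rbind(c(0, 0), c(100, 0))
  tg <- toy_walk_graph(coords, 1, 2, 100)
  stations <- tibble::tibble(
    station_id = c("s_near", "s_on"), line_id = c("l1", "l1"),
    mode = "bus", seq = 1:2, x = c(0, 100), y = c(6, 0)
  )
  g <- attach_stations(tg$graph, stations)
  acc <- g$edges[g$edges$type == "access", ]
  expect_equal(sort(acc$cost_s), c(0, 5))          # 6 m / 1.2 m/s and 0
  expect_equal(g$stations$snap_m, c(6, 0))

  far <- tibble::tibble(station_id = "s_far", line_id = "l1", mode = "bus",
                        seq = 1L, x = 0, y = 1e4)
  expect_error(attach_stations(tg$graph, far), "s_far")
})

test_that("ride edges carry mode speed plus one dwell per stop", {
  # straight corridor with stations 2000 m (bus) and 7000 m (rail) apart
  coords <- rbind(c(0, 0), c(2000, 0), c(9000, 0))
  tg <- toy_walk_graph(coords, c(1, 2), c(2, 3), c(2000, 7000))
  stations <- tibble::tibble(
    station_id = c("b1", "b2", "r1", "r2"),
    line_id = c("bus_l", "bus_l", "rail_l", "rail_l"),
    mode = c("bus", "bus", "rail", "rail"),
    seq = c(1, 2, 1, 2),
    x = c(0, 2000, 2000, 9000), y = 0
  )
  g <- attach_stations(tg$graph, stations) |> add_ride_edges()
  ride <- g$edges[g$edges$type == "ride", ]
  expect_equal(ride$cost_s[ride$length_m == 2000], 2000 / (40 / 3.6) + 30)  # 210 s
  expect_equal(ride$cost_s[ride$length_m == 7000], 7000 / (70 / 3.6) + 30)  # 390 s
})

test_that("riding k segments accumulates k dwell penalties", {
  coords <- rbind(c(0, 0), c(1000, 0), c(2000, 0), c(3000, 0))
  tg <- toy_walk_graph(coords, 1:3, 2:4, rep(1000, 3))
  stations <- tibble::tibble(
    station_id = paste0("s", 1:4), line_id = "l", mode = "bus",
    seq = 1:4, x = c(0, 1000, 2000, 3000), y = 0
  )
  g <- attach_stations(tg$graph, stations) |> add_ride_edges()
  # path cost between end platforms via the reach machinery
  p1 <- g$stations$platform_node[1]
  p4 <- g$stations$platform_node[4]
  rc <- multi_source_reach(g, p1, budget_s = 1e6)
  cost <- rc$node_cost$cost_s[rc$node_cost$node == p4]
  expect_equal(cost, 3000 / (40 / 3.6) + 3 * 30)
})

test_that("single-station lines are rejected", {
  coords <- rbind(c(0, 0), c(500, 0))
  tg <- toy_walk_graph(coords, 1, 2, 500)
  st <- tibble::tibble(station_id = "only", line_id = "l", mode = "bus",
                       seq = 1L, x = 0, y = 0)
  g <- attach_stations(tg$graph, st)
  expect_error(add_ride_edges(g), "fewer than 2")
})

test_that("two lines at one stop transfer through the shared anchor node", {
  coords <- rbind(c(0, 0), c(800, 0))
  tg <- toy_walk_graph(coords, 1, 2, 800)
  stations <- tibble::tibble(
    station_id = c("a_l1", "a_l2", "b_l1", "b_l2"),
    line_id = c("l1", "l2", "l1", "l2"),
    mode = c("bus", "rail", "bus", "rail"),
    seq = c(1, 1, 2, 2),
    x = c(6, 6, 800, 800), y = c(0, 0, 0, 0)
  )
  g <- attach_stations(tg$graph, stations) |> add_ride_edges()
  expect_equal(sum(g$nodes$type == "platform"), 4)
  # transfer between the two co-located platforms costs 2 x access walk
  pa1 <- g$stations$platform_node[g$stations$station_id == "a_l1"]
  pa2 <- g$stations$platform_node[g$stations$station_id == "a_l2"]
  rc <- multi_source_reach(g, pa1, budget_s = 1e6)
  expect_equal(rc$node_cost$cost_s[rc$node_cost$node == pa2],
               2 * 6 / 1.2, tolerance = 1e-9)
})

test_that("alignment polylines lengthen rides and cannot be too short", {
  coords <- rbind(c(0, 0), c(1000, 0))
  tg <- toy_walk_graph(coords, 1, 2, 1000)
  st <- tibble::tibble(station_id = c("s1", "s2"), line_id = "l",
                       mode = "bus", seq = 1:2, x = c(0, 1000), y = 0)
  g <- attach_stations(tg$graph, st)
  # detour alignment: 0 -> (500, 500) -> 1000 is 1000*sqrt(2) long
  detour <- rbind(c(0, 0), c(500, 500), c(1000, 0))
  gr <- add_ride_edges(g, alignments = list(l = detour))
  ride <- gr$edges[gr$edges$type == "ride", ]
  expect_equal(ride$length_m, 1000 * sqrt(2), tolerance = 1e-9)

  short <- rbind(c(0, 0), c(400, 0))   # both stations project near one end
  expect_error(add_ride_edges(g, alignments = list(l = short)), "shorter")
})

test_that("without transit every travel time is the pure walking time", {
  p <- city_params(grid_nx = 6, grid_ny = 6, block_spacing = 400,
                   raster_cell = 200, n_districts = 2,
                   facility_specs = tiny_specs)
  walk <- build_walk_graph(make_grid_walk_network(p))
  withr::local_seed(6)
  for (k in 1:5) {
    pair <- sample(walk$nodes$node, 2)
    rc <- multi_source_reach(walk, pair[1], budget_s = 1e7)
    got <- rc$node_cost$cost_s[rc$node_cost$node == pair[2]]
    a <- walk$nodes[walk$nodes$node == pair[1], ]
    b <- walk$nodes[walk$nodes$node == pair[2], ]
    manhattan <- abs(a$x - b$x) + abs(a$y - b$y)   # grid shortest path
    expect_equal(got, manhattan / 1.2, tolerance = 1e-9)
  }
})

test_that("rail beats bus point-to-point on a shared corridor", {
  coords <- rbind(c(0, 0), c(3000, 0))
  tg <- toy_walk_graph(coords, 1, 2, 3000)
  stations <- tibble::tibble(
    station_id = c("r1", "r2", "b1", "b2"),
    line_id = c("rail_l", "rail_l", "bus_l", "bus_l"),
    mode = c("rail", "rail", "bus", "bus"),
    seq = c(1, 2, 1, 2), x = c(0, 3000, 0, 3000), y = 0
  )
  g <- attach_stations(tg$graph, stations) |> add_ride_edges()
  ride <- g$edges[g$edges$type == "ride", ]
  expect_lt(ride$cost_s[ride$from == g$stations$platform_node[1]],
            ride$cost_s[ride$from == g$stations$platform_node[3]])
})

test_that("validate_graph reports counts, components and orphans", {
  city <- synthetic_city(small_city_params())
  g <- build_multimodal_graph(city)
  rep <- validate_graph(g)
  expect_equal(rep$walk_components, 1L)
  expect_equal(rep$orphan_platforms, 0L)
  expect_equal(rep$negative_costs, 0L)
  expect_equal(unname(rep$node_counts[["walk"]]), 81L)

  walk_only <- build_walk_graph(city$walk_edges)
  rep0 <- validate_graph(walk_only)
  expect_false("platform" %in% names(rep0$node_counts))

  # cost additivity: a sampled path's cost is the sum of its edge costs
  rc <- multi_source_reach(g, g$nodes$node[1], budget_s = 1e7)
  e <- g$edges[g$edges$type == "walk", ][1:3, ]
  expect_equal(sum(e$cost_s), sum(e$length_m) / 1.2, tolerance = 1e-9)
})
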