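test_that("mean nearest-neighbour distance matches direct enumeration", {
  pair <- data.frame(x = c(0, 10), y = c(0, 0))
  expect_equal(mean_nn_distance(pair), 10)
  coll <- data.frame(x = c(0, 3, 10), y = 0)
  expect_equal(mean_nn_distance(coll), 13 / 3)
  expect_error(mean_nn_distance(data.frame(x = 1, y = 1)), "at least 2")
})

test_that("grid-indexed nearest neighbours equal the O(n^2) brute force", {
  withr::local_seed(31)
  for (rep in 1:3) {
    pts <- data.frame(x = runif(200, 0, 5000), y = runif(200, 0, 3000))
    expect_equal(nearest_neighbor_distances(pts), bf_nn_distances(pts),
                 tolerance = 1e-12)
  }
  # clustered pattern stresses the ring search differently
  cl <- sample_facilities(300, "thomas", c(0, 0, 4000, 4000),
                          parents = 4, cluster_sd = 150, seed = 8)
  expect_equal(nearest_neighbor_distances(cl), bf_nn_distances(cl),
               tolerance = 1e-12)
})

test_that("coincident duplicates contribute zero distance with a warning", {
  dup <- data.frame(x = c(1, 1, 5), y = c(2, 2, 2))
  expect_warning(d <- nearest_neighbor_distances(dup), "duplicate")
  expect_equal(d, c(0, 0, 4))
})

test_that("the CSR expectation follows its closed form and scaling law", {
  expect_equal(expected_nn_distance(4, 400), 5)
  expect_equal(expected_nn_distance(100, 1e6), 50)
  expect_equal(expected_nn_distance(10, 2 * 1234) /
                 expected_nn_distance(10, 1234), sqrt(2))
  expect_error(expected_nn_distance(0, 10), ">= 1")
  expect_error(expected_nn_distance(10, 0), "positive")
})

test_that("nn_ratio classifies around 1 and is monotone in r1bar", {
  expect_equal(nn_ratio(5, 5)$classification, "random")
  expect_equal(nn_ratio(5, 5)$R, 1)
  r1 <- seq(0.1, 3, by = 0.1)
  out <- nn_ratio(r1, rep(1, length(r1)))
  expect_true(all(diff(out$R) > 0))
  expect_true(all(out$classification[out$R < 0.99] == "aggregation"))
  expect_true(all(out$classification[out$R > 1.01] == "uniform"))
  expect_error(nn_ratio(1, 0), "positive")
})

test_that("nn_analysis recovers the lattice, CSR and clustered regimes", {
  # square lattice: r1bar = s, rebar = s/2, so R = 2 (small edge bias)
  lat <- sample_facilities(100, "lattice", c(0, 0, 1000, 1000))
  res <- nn_analysis(lat, area = 1e6)
  expect_equal(res$R, 2, tolerance = 0.025)
  expect_equal(res$classification, "uniform")

  # clustered Thomas pattern: R < 1, aggregation
  th <- sample_facilities(200, "thomas", c(0, 0, 10000, 10000),
                          parents = 5, cluster_sd = 200, seed = 4)
  res_th <- nn_analysis(th, area = 1e8)
  expect_lt(res_th$R, 1)
  expect_equal(res_th$classification, "aggregation")

  # CSR: mean R near 1 over replicates (Clark-Evans expectation)
  withr::local_seed(17)
  Rs <- replicate(40, {
    pts <- data.frame(x = runif(300), y = runif(300))
    nn_analysis(pts, area = 1)$R
  })
  expect_gt(mean(Rs), 0.95)
  expect_lt(mean(Rs), 1.05)
})

test_that("the nearest-neighbour ratio is scale-invariant", {
  withr::local_seed(23)
  pts <- data.frame(x = runif(150, 0, 100), y = runif(150, 0, 100))
  base <- nn_analysis(pts, area = 1e4)
  k <- 37
  scaled <- nn_analysis(data.frame(x = pts$x * k, y = pts$y * k),
                        area = 1e4 * k^2)
  expect_equal(scaled$r1bar, base$r1bar * k, tolerance = 1e-12)
  expect_equal(scaled$rebar, base$rebar * k, tolerance = 1e-12)
  expect_equal(scaled$R, base$R, tolerance = 1e-12)
})

test_that("the quartic kernel has the right peak, support and unit mass", {
  ext <- c(0, 0, 1000, 1000)
  r <- 100
  # one point exactly on a cell centre
  pt <- data.frame(x = 505, y = 505)
  k <- kernel_density(pt, radius = r, cell_size = 10, extent = ext)
  cells <- tidy(k)
  at0 <- cells$density[cells$x == 505 & cells$y == 505]
  expect_equal(at0, 3 / (pi * r^2), tolerance = 1e-12)
  far <- cells$density[sqrt((cells$x - 505)^2 + (cells$y - 505)^2) >= r]
  expect_true(all(far == 0))
  # quadrature oracle: the kernel integrates to 1 over its disc
  fine <- kernel_density(pt, radius = r, cell_size = r / 25, extent = ext)
  expect_equal(sum(fine$values) * (r / 25)^2, 1, tolerance = 0.01)
})

test_that("kernel surface mass approximates n for interior patterns", {
  withr::local_seed(5)
  pts <- data.frame(x = runif(40, 300, 700), y = runif(40, 300, 700))
  k <- kernel_density(pts, radius = 150, cell_size = 10,
                      extent = c(0, 0, 1000, 1000))
  expect_equal(sum(k$values) * 100, 40, tolerance = 0.02)
})

test_that("kernel warns when the grid undersamples the kernel", {
  expect_warning(
    kernel_density(data.frame(x = 50, y = 50), radius = 10, cell_size = 20,
                   extent = c(0, 0, 100, 100)),
    "undersampled")
})

test_that("mean centre is the coordinate average", {
  cross <- data.frame(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1))
  expect_equal(mean_center(cross), tibble::tibble(x = 0, y = 0))
  one <- data.frame(x = 3.5, y = -2)
  expect_equal(mean_center(one), tibble::tibble(x = 3.5, y = -2))
  withr::local_seed(3)
  pts <- data.frame(x = runif(50, -1e5, 1e5), y = runif(50, -1e5, 1e5))
  acc <- c(0, 0)
  for (i in 1:50) acc <- acc + c(pts$x[i], pts$y[i])   # streaming oracle
  expect_equal(unlist(mean_center(pts)), c(x = acc[1] / 50, y = acc[2] / 50),
               tolerance = 1e-9)
  expect_error(mean_center(data.frame(x = numeric(0), y = numeric(0))),
               "at least 1")
})

test_that("the deviational ellipse reproduces closed-form patterns", {
  iso <- data.frame(x = c(1, -1, 0, 0), y = c(0, 0, 1, -1))
  e <- standard_deviational_ellipse(iso)
  expect_equal(e$sigma_major, sqrt(0.5), tolerance = 1e-9)
  expect_equal(e$sigma_minor, sqrt(0.5), tolerance = 1e-9)
  expect_equal(unname(e$center), c(0, 0))
  expect_false(e$degenerate)

  line <- data.frame(x = c(-2, 2, -1, 1), y = 0)
  el <- standard_deviational_ellipse(line)
  expect_equal(el$sigma_major, sqrt(2.5), tolerance = 1e-9)
  expect_equal(el$sigma_minor, 0)
  expect_equal(el$rotation, 0)
  expect_true(el$degenerate)

  # sample (n-1) normalisation is available behind ddof
  e1 <- standard_deviational_ellipse(iso, ddof = 1)
  expect_equal(e1$sigma_major, sqrt(2 / 3), tolerance = 1e-9)
})

test_that("the ellipse is equivariant under rotation and keeps its trace", {
  withr::local_seed(12)
  pts <- data.frame(x = rnorm(60, sd = 30), y = rnorm(60, sd = 8))
  base <- standard_deviational_ellipse(pts)
  expect_equal(base$sigma_major^2 + base$sigma_minor^2,
               sum(diag(base$covariance)), tolerance = 1e-9)
  for (theta in c(0.3, 1.2, 2.9)) {
    rot <- data.frame(
      x = cos(theta) * pts$x - sin(theta) * pts$y,
      y = sin(theta) * pts$x + cos(theta) * pts$y
    )
    er <- standard_deviational_ellipse(rot)
    expect_equal(er$sigma_major, base$sigma_major, tolerance = 1e-9)
    expect_equal(er$sigma_minor, base$sigma_minor, tolerance = 1e-9)
    expect_equal(er$rotation, (base$rotation + theta) %% pi, tolerance = 1e-9)
    expect_equal(sum(diag(er$covariance)), sum(diag(base$covariance)),
                 tolerance = 1e-9)
  }
})

test_that("tidiers return one-row summaries", {
  withr::local_seed(2)
  pts <- data.frame(x = runif(30), y = runif(30))
  td <- tidy(nn_analysis(pts, area = 1))
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("n", "area_m2", "r1bar", "rebar", "R", "classification"))
  te <- tidy(standard_deviational_ellipse(pts))
  expect_equal(nrow(te), 1)
})
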