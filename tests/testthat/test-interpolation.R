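test_that("ordinary kriging matches the direct linear-solve oracle", {
  set.seed(101)
  vm <- variogram_model("spherical", nugget = 0.1, sill = 1.2, range = 30)
  worst <- 0
  for (trial in 1:100) {
    n <- sample(3:8, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100); z <- rnorm(n, 10, 3)
    pts <- as_well_table(x, y, v = z)
    spec <- grid_spec(0, 0, 100, 100, cell_size = 50)  # 2 x 2 queries
    g <- krige(pts, "v", vm, spec, compute_variance = TRUE)
    ctr <- aquahazard:::grid_centers(spec)
    for (k in seq_along(ctr$x)) {
      o <- ok_oracle(x, y, z, vm, ctr$x[k], ctr$y[k])
      worst <- max(worst,
                   abs(o$pred - as.vector(g$values)[k]),
                   abs(o$var - as.vector(g$variance)[k]))
      # unbiasedness constraint: oracle weights sum to one
      expect_equal(sum(o$weights), 1, tolerance = 1e-10)
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("kriging with zero nugget is exact at data locations", {
  vm <- variogram_model("spherical", nugget = 0, sill = 2, range = 40)
  x <- c(10, 30, 70, 90); y <- c(10, 80, 20, 90); z <- c(1, 5, 3, 8)
  pts <- as_well_table(x, y, v = z)
  for (k in seq_along(x)) {
    spec <- grid_spec(x[k] - 1, y[k] - 1, x[k] + 1, y[k] + 1, cell_size = 2)
    g <- krige(pts, "v", vm, spec)
    expect_equal(g$values[1, 1], z[k], tolerance = 1e-8)
  }
  expect_error(krige(as_well_table(1, 1, v = 5), "v", vm,
                     grid_spec(0, 0, 10, 10, 5)), "at least 3")
})

test_that("kriging prediction is shift-equivariant (weights sum to 1)", {
  set.seed(5)
  vm <- variogram_model("exponential", nugget = 0.2, sill = 1, range = 25)
  pts <- as_well_table(runif(12, 0, 50), runif(12, 0, 50), v = rnorm(12))
  spec <- grid_spec(0, 0, 50, 50, cell_size = 10)
  g1 <- krige(pts, "v", vm, spec)
  pts2 <- pts; pts2$v <- pts$v + 100
  g2 <- krige(pts2, "v", vm, spec)
  expect_equal(g2$values, g1$values + 100, tolerance = 1e-8)
})

test_that("idw is a convex combination and matches a naive oracle", {
  # two points, equidistant query -> midpoint value for any power
  pts <- as_well_table(c(0, 10), c(0, 0), v = c(0, 10))
  for (p in c(0.5, 1, 2, 4)) {
    g <- idw(pts, "v", power = p, grid_spec(4, -1, 6, 1, 2))
    expect_equal(g$values[1, 1], 5)
  }
  # single point -> constant grid
  g <- idw(as_well_table(5, 5, v = 7), "v", 2, grid_spec(0, 0, 20, 20, 5))
  expect_equal(as.vector(g$values), rep(7, length(g$values)))
  # naive all-pairs re-computation
  set.seed(9)
  n <- 20
  x <- runif(n, 0, 50); y <- runif(n, 0, 50); z <- runif(n, 0, 10)
  pts <- as_well_table(x, y, v = z)
  spec <- grid_spec(0, 0, 50, 50, cell_size = 10)
  g <- idw(pts, "v", 2, spec, max_neighbors = n)
  ctr <- aquahazard:::grid_centers(spec)
  naive <- vapply(seq_along(ctr$x), function(k) {
    d <- sqrt((x - ctr$x[k])^2 + (y - ctr$y[k])^2)
    w <- d^(-2)
    sum(w * z) / sum(w)
  }, numeric(1))
  expect_equal(as.vector(g$values), naive, tolerance = 1e-10)
  # bounded by neighbour values
  expect_true(all(g$values >= min(z) & g$values <= max(z)))
  # exact at a coincident data point
  gq <- idw(pts, "v", 2, grid_spec(x[1] - 1, y[1] - 1, x[1] + 1, y[1] + 1, 2))
  expect_equal(gq$values[1, 1], z[1])
})

test_that("variogram fitting recovers iid and simulated spherical structure", {
  set.seed(31)
  # iid noise: flat variogram, total sill close to the data variance
  pts <- as_well_table(runif(500, 0, 100), runif(500, 0, 100),
                       v = rnorm(500, 0, 2))
  vm <- fit_variogram(pts, "v")
  expect_lt(abs(vm$sill - var(pts$v)) / var(pts$v), 0.2)
  # constant data: degenerate zero-sill model
  cpts <- as_well_table(runif(20, 0, 10), runif(20, 0, 10), v = rep(3, 20))
  vmc <- fit_variogram(cpts, "v")
  expect_true(attr(vmc, "degenerate"))
  expect_equal(vmc$sill, 0)
  expect_error(fit_variogram(cpts[1:5, ], "v"), "at least 10")
  # parameter recovery from a known spherical model
  true_vm <- variogram_model("spherical", nugget = 0.1, sill = 1.1, range = 30)
  n <- 1000
  x <- runif(n, 0, 150); y <- runif(n, 0, 150)
  C <- aquahazard:::vgm_cov(true_vm, as.matrix(dist(cbind(x, y))))
  diag(C) <- true_vm$sill
  z <- as.vector(t(chol(C + diag(1e-10, n))) %*% rnorm(n))
  vf <- fit_variogram(as_well_table(x, y, v = z), "v", model = "spherical")
  expect_lt(abs(vf$range - true_vm$range) / true_vm$range, 0.30)
  expect_lt(abs(vf$sill - true_vm$sill) / true_vm$sill, 0.30)
})

test_that("leave-one-out identity matches per-point refits", {
  set.seed(17)
  vm <- variogram_model("spherical", nugget = 0.1, sill = 1.2, range = 30)
  n <- 25
  x <- runif(n, 0, 100); y <- runif(n, 0, 100)
  C <- aquahazard:::vgm_cov(vm, as.matrix(dist(cbind(x, y))))
  diag(C) <- vm$sill
  z <- as.vector(t(chol(C)) %*% rnorm(n)) + 5
  pts <- as_well_table(x, y, v = z)
  fast <- as.numeric(loo_standardized_rmse(pts, "v", vm))
  brute <- sqrt(mean(vapply(seq_len(n), function(i) {
    o <- ok_oracle(x[-i], y[-i], z[-i], vm, x[i], y[i])
    (z[i] - o$pred)^2 / o$var
  }, numeric(1))))
  expect_equal(fast, brute, tolerance = 1e-10)
  expect_error(loo_standardized_rmse(pts[1:5, ], "v", vm), "at least 10")
})

test_that("grid cells partition across districts without double counting", {
  w <- small_world()
  spec <- grid_spec_for(w$districts, 8)
  g <- structure(list(parameter = "Chloride", spec = spec,
                      values = matrix(1, spec$n_rows, spec$n_cols),
                      variance = NULL, method = "idw"),
                 class = "parameter_grid")
  vals <- grid_to_district_values(g, w$districts)
  expect_identical(sum(lengths(vals)), spec$n_rows * spec$n_cols)
  # two half-plane districts of equal area get equal cell counts
  dm2 <- generate_districts(2, seed = 1, extent = c(0, 0, 100, 100),
                            total_population = 1000)
  dm2$districts$seed_x <- c(25, 75); dm2$districts$seed_y <- c(50, 50)
  spec2 <- grid_spec(0, 0, 100, 100, 10)
  g2 <- structure(list(parameter = "x", spec = spec2,
                       values = matrix(0, 10, 10), variance = NULL,
                       method = "idw"), class = "parameter_grid")
  v2 <- grid_to_district_values(g2, dm2)
  expect_equal(lengths(v2)[[1]], lengths(v2)[[2]])
})
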