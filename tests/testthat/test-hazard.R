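test_that("exceedance fractions count strict violations", {
  std <- load_standards()
  cl <- standards_entry(std, "Chloride")
  fe <- standards_entry(std, "Iron")
  expect_equal(exceedance_fraction(c(300, 200, 100), cl), 1 / 3)
  expect_equal(exceedance_fraction(c(300, 400), cl), 1)
  expect_equal(exceedance_fraction(c(0.1, 0.5), fe), 0.5)
  expect_error(exceedance_fraction(numeric(0), cl))
})

test_that("the hazard index is the mean violation proportion", {
  p10 <- index_parameters()
  expect_equal(hazard_index(setNames(rep(1, 10), p10)), 1)
  expect_equal(hazard_index(setNames(c(1, rep(0, 9)), p10)), 0.1)
  set.seed(4)
  for (k in 1:20) {
    f <- setNames(runif(10), p10)
    expect_equal(hazard_index(f), sum(f) / 10, tolerance = 1e-15)
  }
  expect_error(hazard_index(setNames(runif(9), p10[-1])), "Chloride")
})

test_that("hazard classes use the documented bins", {
  expect_equal(as.character(classify_hazard(c(0.09, 0.37, 0.10, 0.199, 0.2, 0.31))),
               c("low", "very_high", "moderate", "moderate", "high", "very_high"))
  expect_error(classify_hazard(1.2))
  expect_error(classify_hazard(0.5, breaks = c(0.3, 0.2, 0.1)))
})

test_that("grid-based hazard equals exhaustive enumeration on toy worlds", {
  std <- load_standards()
  p10 <- index_parameters()
  set.seed(77)
  for (trial in 1:20) {
    nd <- sample(2:4, 1)
    dm <- generate_districts(nd, seed = trial, extent = c(0, 0, 40, 60),
                             total_population = 1000)
    spec <- grid_spec(0, 0, 40, 60, cell_size = 10)  # 24 cells
    grids <- lapply(p10, function(p) {
      lim <- std$limit[std$parameter == p]
      structure(list(parameter = p, spec = spec,
                     values = matrix(runif(24, 0, 2 * lim), 6, 4),
                     variance = NULL, method = "idw"),
                class = "parameter_grid")
    })
    hz <- hazard_by_interpolation(grids, dm, std)
    ctr <- aquahazard:::grid_centers(spec)
    dix <- assign_district(dm, ctr$x, ctr$y)
    for (r in seq_len(nrow(hz))) {
      d <- which(dm$districts$id == hz$district[r])
      sel <- dix == d
      fr <- vapply(seq_along(p10), function(k)
        mean(violates(as.vector(grids[[k]]$values)[sel],
                      standards_entry(std, p10[k]))), numeric(1))
      expect_equal(hz$index[r], mean(fr), tolerance = 1e-15)
      expect_equal(unlist(hz[r, p10], use.names = FALSE), fr)
    }
  }
})

test_that("well-based hazard does direct arithmetic and flags low support", {
  std <- load_standards()
  p10 <- index_parameters()
  dm <- generate_districts(2, seed = 1, extent = c(0, 0, 40, 40),
                           total_population = 100)
  w <- as_well_table(x = c(5, 6), y = c(5, 6))
  for (p in p10) w[[p]] <- rep(std$limit[std$parameter == p] / 2, 2)
  w$Iron <- c(0.6, 0.6)      # above 0.3, compliant under the reversed rule
  w$Chloride <- c(300, 100)  # one violation of 250 among two wells
  w$district <- dm$districts$id[assign_district(dm, w$x, w$y)]
  hz <- hazard_by_imputation(w, dm, std)
  expect_equal(nrow(hz), 1L)  # empty district excluded
  expect_equal(hz$Chloride, 0.5)
  expect_equal(hz$index, 0.05)
  expect_true(hz$low_support)   # fewer than 5 wells
  expect_equal(hz$n_units, 2L)
  expect_error(hazard_by_imputation(w[0, ], dm, std))
})

test_that("both pathways agree on densely sampled synthetic data", {
  w <- small_world()
  imp <- rf_impute(w$wells, n_trees = 50, seed = 3)
  hz_imp <- hazard_by_imputation(imp, w$districts, w$standards)
  tr <- true_district_exceedance(w$fields, w$districts, w$standards)
  m <- match(hz_imp$district, tr$district)
  expect_lt(max(abs(hz_imp$index - tr$index[m])), 0.12)
  expect_true(all(hz_imp$index >= 0 & hz_imp$index <= 1))
})

test_that("the exceedance table scales to percent and sorts by index", {
  std <- load_standards()
  dm <- generate_districts(3, seed = 2, extent = c(0, 0, 60, 60),
                           total_population = 100)
  p10 <- index_parameters()
  set.seed(6)
  w <- as_well_table(x = runif(30, 0, 60), y = runif(30, 0, 60))
  for (p in p10)
    w[[p]] <- runif(30, 0, 2 * std$limit[std$parameter == p])
  w$district <- dm$districts$id[assign_district(dm, w$x, w$y)]
  hz <- hazard_by_imputation(w, dm, std)
  tab <- exceedance_table(hz)
  expect_equal(dim(tab), c(nrow(hz), 12L))  # district + 10 params + index
  expect_true(all(diff(tab$index) <= 0))
  k <- match(tab$district[1], hz$district)
  expect_equal(unlist(tab[1, p10], use.names = FALSE),
               100 * unlist(hz[k, p10], use.names = FALSE))
})

test_that("district labels only relabel hazard results", {
  w <- small_world()
  imp <- rf_impute(w$wells, n_trees = 30, seed = 8)
  hz <- hazard_by_imputation(imp, w$districts, w$standards)
  perm <- w$districts
  shuffle <- c(2, 1, seq_len(nrow(perm$districts))[-(1:2)])
  perm$districts <- perm$districts[shuffle, ]
  perm$polygons <- perm$polygons[perm$districts$id]
  hz2 <- hazard_by_imputation(imp, perm, w$standards)
  m <- match(hz$district, hz2$district)
  expect_equal(hz$index, hz2$index[m])
})

test_that("population exposure is all-or-nothing with an exact national summary", {
  w <- small_world()
  imp <- rf_impute(w$wells, n_trees = 30, seed = 4)
  hz <- hazard_by_imputation(imp, w$districts, w$standards)
  ex0 <- population_exposure(hz, w$districts, exposure_threshold = 0)
  expect_equal(attr(ex0, "national_percent"),
               100 * sum(w$districts$districts$population[
                 match(hz$district[hz$index > 0], w$districts$districts$id)]) /
                 sum(w$districts$districts$population))
  ex1 <- population_exposure(hz, w$districts, exposure_threshold = 1)
  expect_equal(attr(ex1, "national_exposed"), 0)
  exm <- population_exposure(hz, w$districts, 0.2)
  expect_true(all(exm$exposed %in% c(0, exm$population)))
  expect_lte(attr(exm, "national_exposed"), attr(exm, "national_total"))
  expect_equal(attr(exm, "national_percent"),
               100 * attr(exm, "national_exposed") / attr(exm, "national_total"))
  # adding a compliant value never increases an exceedance fraction
  std <- w$standards
  cl <- standards_entry(std, "Chloride")
  vals <- c(300, 100, 260)
  expect_lte(exceedance_fraction(c(vals, 10), cl), exceedance_fraction(vals, cl))
})
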