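test_that("district tessellation partitions the study rectangle", {
  dm <- generate_districts(25, seed = 1)
  expect_equal(nrow(dm$districts), 25L)
  expect_equal(sum(dm$districts$area_km2), 250 * 420, tolerance = 1e-3)
  dm2 <- generate_districts(2, seed = 7)
  expect_equal(sum(dm2$districts$area_km2), 250 * 420, tolerance = 1e-3)
  # determinism
  dm_again <- generate_districts(25, seed = 1)
  expect_identical(dm, dm_again)
  expect_error(generate_districts(1, seed = 1))
})

test_that("district populations are non-negative and sum exactly to the total", {
  dm <- generate_districts(25, seed = 3, total_population = 22e6)
  expect_true(all(dm$districts$population >= 0))
  expect_identical(sum(dm$districts$population), 22000000L)
  expect_setequal(unique(dm$districts$climate_zone),
                  c("dry", "intermediate", "wet"))
})

test_that("realized zone means are calibrated to the targets", {
  w <- small_world()
  zm <- zone_mean_table()
  for (p in c("Chloride", "Fluoride", "TDS")) {
    for (z in c("dry", "intermediate", "wet")) {
      realized <- mean(w$fields$values[[p]][w$fields$cell_zone == z])
      target <- zm[zm$parameter == p, z]
      expect_lt(abs(realized - target) / target, 0.05,
                label = paste(p, z, "relative error"))
    }
  }
  expect_true(all(unlist(w$fields$values) > 0))
})

test_that("zero-cv fields are piecewise constant at zone means", {
  dm <- generate_districts(4, seed = 5, extent = c(0, 0, 60, 100),
                           total_population = 1e5)
  f <- generate_true_fields(dm, cv = 0, seed = 6, cell_size = 5)
  zm <- zone_mean_table()
  for (z in unique(as.vector(f$cell_zone))) {
    vals <- f$values$Chloride[f$cell_zone == z]
    expect_equal(vals, rep(zm[zm$parameter == "Chloride", z], length(vals)))
  }
})

test_that("well sampling is deterministic and complete", {
  w <- small_world()
  again <- sample_wells(w$fields, w$districts, 300, seed = 13)
  expect_identical(w$wells_complete, again)
  one <- sample_wells(w$fields, w$districts, 1, seed = 2)
  expect_equal(nrow(one), 1L)
  expect_false(anyNA(one[index_parameters()]))
  # coordinates inside the rectangle and consistent district assignment
  e <- w$districts$extent
  expect_true(all(w$wells_complete$x >= e[1] & w$wells_complete$x <= e[3]))
  expect_true(all(w$wells_complete$y >= e[2] & w$wells_complete$y <= e[4]))
  dix <- assign_district(w$districts, w$wells_complete$x, w$wells_complete$y)
  expect_identical(w$districts$districts$id[dix], w$wells_complete$district)
})

test_that("missingness is MCAR at the configured rates and reproducible", {
  dm <- generate_districts(8, seed = 21)
  f <- generate_true_fields(dm, seed = 22, cell_size = 5)
  wc <- sample_wells(f, dm, 2000, seed = 23)
  rates <- default_missingness_rates()
  wm <- apply_missingness(wc, rates, seed = 24)
  for (p in names(rates)) {
    got <- mean(is.na(wm[[p]]))
    se <- sqrt(rates[[p]] * (1 - rates[[p]]) / 2000)
    expect_lt(abs(got - rates[[p]]), 4 * se + 1e-9, label = p)
  }
  expect_identical(wm, apply_missingness(wc, rates, seed = 24))
  # observed cells untouched, rate 0 is identity
  expect_identical(apply_missingness(wc, c(Chloride = 0), seed = 1), wc)
  expect_error(apply_missingness(wc, c(Chloride = 1), seed = 1))
})

test_that("default missingness rates mirror the survey sample counts", {
  r <- default_missingness_rates()
  expect_equal(unname(r["Phosphate"]), 1 - 199 / 688)
  expect_equal(unname(r["Hardness"]), 1 - 659 / 688)
  expect_true(all(r >= 0 & r < 1))
})

test_that("true district exceedance is exact on constructed fields", {
  w <- small_world()
  std <- w$standards
  f <- w$fields
  cl <- standards_entry(std, "Chloride")
  # everywhere above the limit
  f_hi <- f; f_hi$values$Chloride[] <- cl$limit * 2
  tr <- true_district_exceedance(f_hi, w$districts, std)
  expect_equal(tr$Chloride, rep(1, nrow(tr)))
  # everywhere compliant
  f_lo <- f; f_lo$values$Chloride[] <- cl$limit / 2
  tr <- true_district_exceedance(f_lo, w$districts, std)
  expect_equal(tr$Chloride, rep(0, nrow(tr)))
  # vertical half-plane split of the whole rectangle
  ctr <- aquahazard:::grid_centers(f$spec)
  half <- matrix(ifelse(ctr$x > mean(range(ctr$x)), cl$limit * 2, 0),
                 f$spec$n_rows, f$spec$n_cols)
  f_half <- f; f_half$values$Chloride <- half
  tr <- true_district_exceedance(f_half, w$districts, std)
  overall <- sum(tr$Chloride * tabulate(as.vector(f$cell_district),
                                        nrow(tr))) /
    length(f$cell_district)
  # exact: the population-weighted mean equals the fraction of grid
  # centres right of the midline (12/25 columns here)
  expect_equal(overall, mean(ctr$x > mean(range(ctr$x))))
})
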