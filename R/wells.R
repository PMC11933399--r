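#' Sample wells from true fields
#'
#' Places `n_wells` wells in the study rectangle (uniformly at random, or
#' population-weighted across districts), reads each index parameter off
#' the true field at the well's cell, and perturbs it with small
#' multiplicative lognormal measurement noise (mean one). The returned
#' table is complete; use [apply_missingness()] to emulate survey gaps.
#'
#' @param fields A `"true_fields"` object.
#' @param districts The matching `"district_map"`.
#' @param n_wells Number of wells (default 688, a realistic national
#'   water-supply-well network size).
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of the measurement noise
#'   (default 0.05).
#' @param population_weighted If `TRUE`, wells are distributed across
#'   districts proportionally to population instead of uniformly in space.
#' @return A `"well_table"` data.frame: `well_id`, `x`, `y`, `district`,
#'   `climate_zone`, `depth` (m), and one column per index parameter
#'   (mg/L).
#' @export
sample_wells <- function(fields, districts, n_wells = 688, seed = 1,
                         noise_cv = 0.05, population_weighted = FALSE) {
  stopifnot(inherits(fields, "true_fields"), n_wells >= 1)
  set.seed(seed)
  e <- districts$extent
  if (population_weighted) {
    d <- districts$districts
    target <- sample(seq_len(nrow(d)), n_wells, replace = TRUE,
                     prob = d$population)
    x <- y <- numeric(n_wells)
    for (k in seq_len(n_wells)) {   # rejection sample inside the district
      repeat {
        px <- stats::runif(1, e[1], e[3]); py <- stats::runif(1, e[2], e[4])
        if (assign_district(districts, px, py) == target[k]) break
      }
      x[k] <- px; y[k] <- py
    }
  } else {
    x <- stats::runif(n_wells, e[1], e[3])
    y <- stats::runif(n_wells, e[2], e[4])
  }
  dix <- assign_district(districts, x, y)
  cell <- grid_cell_of(fields$spec, x, y)
  idx <- cbind(cell$row, cell$col)
  s <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  wells <- data.frame(
    well_id = sprintf("W%04d", seq_len(n_wells)),
    x = x, y = y,
    district = districts$districts$id[dix],
    climate_zone = districts$districts$climate_zone[dix],
    depth = pmin(pmax(stats::rlnorm(n_wells, log(40), 0.35), 4), 105),
    stringsAsFactors = FALSE
  )
  for (p in names(fields$values)) {
    v <- fields$values[[p]][idx]
    if (s > 0) v <- v * exp(stats::rnorm(n_wells, -s^2 / 2, s))
    wells[[p]] <- v
  }
  class(wells) <- c("well_table", "data.frame")
  wells
}

#' Delete values completely at random
#'
#' Emulates per-parameter survey gaps by deleting each parameter's values
#' independently (MCAR) at the given rates. The input table is not
#' modified.
#'
#' @param wells A `"well_table"`.
#' @param rates Named numeric vector of missingness fractions in `[0, 1)`,
#'   one entry per parameter column to degrade. Defaults to
#'   [default_missingness_rates()].
#' @param seed Integer seed; the same seed deletes the same cells.
#' @return A new `"well_table"` with `NA`s inserted.
#' @export
apply_missingness <- function(wells, rates = default_missingness_rates(),
                              seed = 1) {
  stopifnot(inherits(wells, "data.frame"))
  if (any(rates < 0 | rates >= 1))
    stop("missingness rates must be in [0, 1)")
  out <- wells
  set.seed(seed)
  for (p in names(rates)) {
    if (!p %in% names(out)) stop("no column '", p, "' in well table")
    drop <- stats::runif(nrow(out)) < rates[[p]]
    out[[p]][drop] <- NA_real_
  }
  out
}

#' Default per-parameter missingness rates
#'
#' Rates derived from the per-parameter sample counts of the national
#' groundwater survey the generator emulates (688 georeferenced wells, but
#' as few as 199 Phosphate and as many as 659 Hardness measurements):
#' `rate = 1 - n_observed / n_total`, i.e. about 71% missing Phosphate and
#' 4% missing Hardness.
#'
#' @param counts Named integer vector of observed sample counts per
#'   parameter.
#' @param n_total Total number of wells (default 688).
#' @return Named numeric vector of missingness fractions.
#' @export
default_missingness_rates <- function(counts = default_sample_counts(),
                                      n_total = 688) {
  if (any(counts > n_total)) stop("counts cannot exceed n_total")
  r <- 1 - counts / n_total
  r
}

#' @rdname default_missingness_rates
#' @export
default_sample_counts <- function() {
  c(Chloride = 598, Alkalinity = 613, Nitrate = 316, Nitrite = 208,
    Fluoride = 613, Phosphate = 199, TDS = 348, Hardness = 659,
    Iron = 620, Sulphate = 437)
}
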