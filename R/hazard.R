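#' Collect grid values by district
#'
#' Assigns every cell centre of an interpolated grid to the district
#' containing it and returns the per-district value lists. Cells outside
#' all districts are dropped; districts with no cell centres are flagged
#' with a warning and omitted.
#'
#' @param grid A `"parameter_grid"`.
#' @param districts A `"district_map"` in the same coordinate frame.
#' @return Named list (district id) of numeric vectors.
#' @export
grid_to_district_values <- function(grid, districts) {
  stopifnot(inherits(grid, "parameter_grid"))
  ctr <- grid_centers(grid$spec)
  dix <- assign_district(districts, ctr$x, ctr$y)
  v <- as.vector(grid$values)
  keep <- !is.na(dix)
  out <- split(v[keep], factor(districts$districts$id[dix[keep]],
                               levels = districts$districts$id))
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty) > 0) {
    warning("district(s) with no grid cells excluded: ",
            paste(empty, collapse = ", "))
    out <- out[lengths(out) > 0L]
  }
  out
}

#' Fraction of values violating a standard
#'
#' @param values Non-empty numeric vector with no missing values.
#' @param entry A one-row standards entry.
#' @return Fraction in `[0, 1]`.
#' @export
exceedance_fraction <- function(values, entry) {
  if (length(values) == 0L) stop("empty value list")
  mean(violates(values, entry))
}

#' Composite multi-parameter hazard index
#'
#' The hazard index of a district is the arithmetic mean, over the index
#' parameters, of the within-district proportion of grid cells (or wells)
#' whose concentration violates the drinking-water standard. It therefore
#' lies in `[0, 1]`.
#'
#' @param exceedances Named numeric vector of per-parameter violation
#'   fractions.
#' @param params Parameter set (default the ten index parameters).
#' @return Numeric scalar in `[0, 1]`.
#' @export
hazard_index <- function(exceedances, params = index_parameters()) {
  miss <- setdiff(params, names(exceedances))
  if (length(miss) > 0)
    stop("missing exceedance fraction for: ", paste(miss, collapse = ", "))
  mean(exceedances[params])
}

.hazard_results <- function(value_lists_by_param, districts, standards,
                            method, min_units_flag = 5L) {
  params <- names(value_lists_by_param)
  ids <- Reduce(union, lapply(value_lists_by_param, names))
  ids <- districts$districts$id[districts$districts$id %in% ids]
  rows <- lapply(ids, function(id) {
    ex <- vapply(params, function(p) {
      v <- value_lists_by_param[[p]][[id]]
      if (is.null(v) || length(v) == 0L) return(NA_real_)
      exceedance_fraction(v, standards_entry(standards, p))
    }, numeric(1))
    n_units <- max(vapply(params, function(p)
      length(value_lists_by_param[[p]][[id]]), integer(1)))
    if (anyNA(ex)) return(NULL)
    data.frame(district = id, method = method, t(ex),
               index = hazard_index(ex, params),
               n_units = n_units,
               low_support = n_units < min_units_flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("hazard_result", "data.frame")
  out
}

#' Hazard index from interpolated grids (interpolated method)
#'
#' @param grids Named list of `"parameter_grid"` objects (one per index
#'   parameter, shared grid spec).
#' @param districts A `"district_map"`.
#' @param standards A `"standards"` table.
#' @return A `"hazard_result"` data.frame: `district`, `method`, one
#'   fraction column per parameter, `index`, `n_units`, `low_support`.
#' @export
hazard_by_interpolation <- function(grids, districts, standards) {
  stopifnot(length(grids) > 0)
  params <- vapply(grids, function(g) g$parameter, character(1))
  names(grids) <- params
  vals <- lapply(grids, grid_to_district_values, districts = districts)
  .hazard_results(vals, districts, standards, method = "interpolated")
}

#' Hazard index from imputed well records (imputed method)
#'
#' @param imputed An `"rf_imputation"` result or a completed
#'   `"well_table"` with district assignments and no missing index values.
#' @param districts A `"district_map"`.
#' @param standards A `"standards"` table.
#' @param parameters Parameters to score (default: index parameters
#'   present in the table).
#' @return A `"hazard_result"` data.frame (districts with zero wells
#'   excluded; districts with fewer than 5 wells flagged `low_support`).
#' @export
hazard_by_imputation <- function(imputed, districts, standards,
                                 parameters = NULL) {
  wells <- if (inherits(imputed, "rf_imputation")) imputed$completed else imputed
  if (nrow(wells) == 0L) stop("empty well table")
  if (is.null(parameters))
    parameters <- intersect(index_parameters(), names(wells))
  if (anyNA(wells[parameters]))
    stop("well table has missing index values; impute first")
  f <- factor(wells$district, levels = districts$districts$id)
  vals <- lapply(parameters, function(p) {
    out <- split(wells[[p]], f)
    out[lengths(out) > 0L]
  })
  names(vals) <- parameters
  .hazard_results(vals, districts, standards, method = "imputed")
}

#' District x parameter exceedance table (percent)
#'
#' @param results A `"hazard_result"` data.frame.
#' @return data.frame of percentages (fractions x 100), one row per
#'   district, sorted by descending index; row "shares" are not normalized.
#' @export
exceedance_table <- function(results) {
  stopifnot(nrow(results) > 0)
  params <- setdiff(names(results),
                    c("district", "method", "index", "n_units", "low_support"))
  out <- results[order(-results$index),
                 c("district", params, "index"), drop = FALSE]
  out[params] <- out[params] * 100
  out$index <- out$index
  rownames(out) <- NULL
  out
}

#' Classify a hazard index value
#'
#' @param index Numeric vector in `[0, 1]`.
#' @param breaks Ascending thresholds between low/moderate/high/very_high
#'   (default `c(0.10, 0.20, 0.30)`; a boundary value belongs to the upper
#'   class).
#' @return Ordered factor.
#' @export
classify_hazard <- function(index, breaks = c(0.10, 0.20, 0.30)) {
  if (any(index < 0 | index > 1)) stop("hazard index must lie in [0, 1]")
  if (is.unsorted(breaks, strictly = TRUE) || length(breaks) != 3)
    stop("breaks must be 3 ascending thresholds")
  cut(index, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("low", "moderate", "high", "very_high"),
      ordered_result = TRUE)
}

#' District and national population exposure
#'
#' A district's entire population counts as exposed if and only if its
#' hazard index exceeds `exposure_threshold` (all-or-nothing at district
#' resolution, on total population regardless of actual drinking-water
#' source). No threshold is canonical; the default of 0.2 (the
#' moderate/high class boundary) must be reviewed for any real
#' application.
#'
#' @param results A `"hazard_result"` data.frame for one method.
#' @param districts A `"district_map"` covering every result district.
#' @param exposure_threshold Index cutoff in `[0, 1]` (default 0.2).
#' @return An `"exposure_result"` data.frame (`district`, `population`,
#'   `index`, `exposed`) with attributes `national_total`,
#'   `national_exposed` and `national_percent`
#'   (`100 * national_exposed / national_total`).
#' @export
population_exposure <- function(results, districts, exposure_threshold = 0.2) {
  if (exposure_threshold < 0 || exposure_threshold > 1)
    stop("exposure_threshold must lie in [0, 1]")
  d <- districts$districts
  i <- match(results$district, d$id)
  if (anyNA(i)) stop("result district(s) absent from the map: ",
                     paste(results$district[is.na(i)], collapse = ", "))
  pop <- d$population[i]
  if (anyNA(pop)) stop("district population missing")
  exposed <- ifelse(results$index > exposure_threshold, pop, 0L)
  out <- data.frame(district = results$district, population = pop,
                    index = results$index, exposed = exposed,
                    stringsAsFactors = FALSE)
  class(out) <- c("exposure_result", "data.frame")
  attr(out, "national_total") <- sum(d$population)
  attr(out, "national_exposed") <- sum(exposed)
  attr(out, "national_percent") <- 100 * sum(exposed) / sum(d$population)
  attr(out, "exposure_threshold") <- exposure_threshold
  out
}
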