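#' Climate-zone mean concentrations
#'
#' Default calibration targets for the synthetic concentration fields: the
#' mean of each index parameter within the dry, intermediate and wet
#' climate zones (mg/L). Values reflect the national groundwater survey
#' the generator emulates — salinity-related parameters (Chloride, TDS,
#' Hardness, Sulphate, Alkalinity) are highest in the dry zone where
#' evaporative concentration and water-rock interaction dominate, while
#' Nitrite is highest in the wet zone.
#'
#' @return data.frame with columns `parameter`, `dry`, `intermediate`,
#'   `wet`.
#' @export
zone_mean_table <- function() {
  data.frame(
    parameter = index_parameters(),
    dry          = c(279.2, 262.9, 2.5, 0.1, 1.0, 0.7, 875.3, 343.2, 2.3, 54.4),
    intermediate = c(129.0, 193.2, 2.9, 0.5, 0.7, 0.6, 436.2, 234.4, 3.3, 32.0),
    wet          = c(60.2, 104.9, 2.8, 1.3, 0.5, 0.4, 178.7, 127.3, 2.6, 18.4),
    stringsAsFactors = FALSE
  )
}

#' Default inter-parameter correlation clusters
#'
#' Parameters within one cluster share a latent spatial field, emulating
#' the strong empirical clustering of groundwater chemistry: a salinity
#' cluster (Chloride, TDS, Hardness, Sulphate, Alkalinity), a nutrient
#' cluster (Nitrate, Nitrite, Phosphate), and independent Fluoride and
#' Iron (distinct geogenic sources).
#'
#' @return Named list of character vectors.
#' @export
default_parameter_clusters <- function() {
  list(
    salinity = c("Chloride", "TDS", "Hardness", "Sulphate", "Alkalinity"),
    nutrient = c("Nitrate", "Nitrite", "Phosphate"),
    fluoride = "Fluoride",
    iron     = "Iron"
  )
}

# Stationary standard-normal Gaussian random field on an n_rows x n_cols
# grid with Gaussian correlation exp(-(h / L)^2), by FFT convolution of
# white noise with a Gaussian kernel on a padded torus.
.grf <- function(n_rows, n_cols, cell_size, corr_length) {
  s <- corr_length / 2 / cell_size          # kernel sd in cells
  pad <- ceiling(3.5 * s)
  nr <- stats::nextn(n_rows + 2 * pad, c(2, 3, 5))
  nc <- stats::nextn(n_cols + 2 * pad, c(2, 3, 5))
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  K <- exp(-outer(di^2, dj^2, "+") / (2 * s^2))
  K <- K / sqrt(sum(K^2))                   # unit marginal variance
  W <- matrix(stats::rnorm(nr * nc), nr, nc)
  F <- Re(stats::fft(stats::fft(W) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  F[seq_len(n_rows), seq_len(n_cols)]
}

#' Simulate true concentration fields
#'
#' For each index parameter, generates a spatially autocorrelated lognormal
#' concentration raster over the district map: a latent Gaussian random
#' field (shared within correlation clusters) modulates zone-specific mean
#' levels multiplicatively. Realized zone means are calibrated exactly to
#' the `zone_means` targets by a per-zone rescale, so the targets hold at
#' any noise level. All concentrations are strictly positive; `cv = 0`
#' degenerates to fields piecewise-constant at the zone means.
#'
#' @param districts A `"district_map"`.
#' @param zone_means data.frame as [zone_mean_table()]; must cover every
#'   (parameter, zone) pair.
#' @param correlation_length Spatial correlation length in km (default 40).
#' @param cv Within-zone coefficient of variation of the lognormal field
#'   (default 0.8).
#' @param seed Integer seed.
#' @param cell_size Raster resolution in km (default 2).
#' @param clusters Correlation clusters, see [default_parameter_clusters()].
#' @param cluster_cor Correlation of each parameter's latent field with its
#'   cluster's shared field (default 0.8).
#' @return A `"true_fields"` object: `spec` (grid), `values` (named list of
#'   n_rows x n_cols matrices), `cell_district` (integer matrix of district
#'   indices), plus the generating settings.
#' @export
generate_true_fields <- function(districts,
                                 zone_means = zone_mean_table(),
                                 correlation_length = 40,
                                 cv = 0.8,
                                 seed = 1,
                                 cell_size = 2,
                                 clusters = default_parameter_clusters(),
                                 cluster_cor = 0.8) {
  stopifnot(inherits(districts, "district_map"), cv >= 0)
  params <- zone_means$parameter
  zones <- c("dry", "intermediate", "wet")
  if (!all(zones %in% names(zone_means)))
    stop("zone_means must have columns dry, intermediate, wet")
  if (anyNA(zone_means[zones])) {
    bad <- which(is.na(as.matrix(zone_means[zones])), arr.ind = TRUE)
    stop("missing zone mean for ", params[bad[1, 1]], " / ", zones[bad[1, 2]])
  }

  spec <- grid_spec_for(districts, cell_size)
  ctr <- grid_centers(spec)
  dix <- assign_district(districts, ctr$x, ctr$y)
  cell_district <- matrix(dix, spec$n_rows, spec$n_cols)
  cell_zone <- matrix(districts$districts$climate_zone[dix],
                      spec$n_rows, spec$n_cols)

  set.seed(seed)
  latent <- lapply(clusters, function(p) .grf(spec$n_rows, spec$n_cols,
                                              cell_size, correlation_length))
  sigma <- sqrt(log(1 + cv^2))
  values <- vector("list", length(params)); names(values) <- params
  for (p in params) {
    cl <- which(vapply(clusters, function(v) p %in% v, logical(1)))
    if (length(cl) != 1L) stop("parameter '", p, "' must be in exactly one cluster")
    Z <- if (cv == 0) {
      matrix(0, spec$n_rows, spec$n_cols)
    } else if (length(clusters[[cl]]) > 1L) {
      sqrt(cluster_cor) * latent[[cl]] +
        sqrt(1 - cluster_cor) * .grf(spec$n_rows, spec$n_cols,
                                     cell_size, correlation_length)
    } else {
      latent[[cl]]
    }
    m <- zone_means[zone_means$parameter == p, zones]
    base <- matrix(as.numeric(m[match(cell_zone, zones)]),
                   spec$n_rows, spec$n_cols)
    f <- base * exp(sigma * Z - sigma^2 / 2)
    for (z in zones) {        # exact zone-mean calibration
      sel <- cell_zone == z
      if (any(sel)) f[sel] <- f[sel] * as.numeric(m[[z]]) / mean(f[sel])
    }
    values[[p]] <- f
  }
  structure(list(spec = spec, values = values, cell_district = cell_district,
                 cell_zone = cell_zone, zone_means = zone_means,
                 correlation_length = correlation_length, cv = cv,
                 clusters = clusters, cluster_cor = cluster_cor, seed = seed),
            class = "true_fields")
}

#' Ground-truth district exceedance from dense fields
#'
#' Exhaustively evaluates every raster cell of the true fields against the
#' standards and returns the per-district, per-parameter violation
#' fraction together with the composite hazard index (their mean). This is
#' the oracle that the interpolation and imputation pathways are expected
#' to recover.
#'
#' @param fields A `"true_fields"` object.
#' @param districts The `"district_map"` used to generate the fields.
#' @param standards A `"standards"` table.
#' @return data.frame: `district`, one fraction column per parameter,
#'   `index`.
#' @export
true_district_exceedance <- function(fields, districts, standards) {
  stopifnot(inherits(fields, "true_fields"))
  d <- districts$districts
  params <- names(fields$values)
  dix <- as.vector(fields$cell_district)
  out <- data.frame(district = d$id, stringsAsFactors = FALSE)
  for (p in params) {
    v <- violates(as.vector(fields$values[[p]]), standards_entry(standards, p))
    out[[p]] <- as.numeric(tapply(v, factor(dix, levels = seq_len(nrow(d))),
                                  mean))
  }
  out$index <- rowMeans(out[params])
  out
}
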