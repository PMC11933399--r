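#' Generate a synthetic district map
#'
#' Builds a Voronoi tessellation of `n_districts` random seed points over a
#' fixed study rectangle (default 250 km x 420 km, roughly the extent of
#' Sri Lanka), assigns each district to a climate zone by a smooth
#' north/east "dryness" gradient (so zones are spatially contiguous), and
#' allocates a national population total across districts with density
#' highest in the wet (southwest) zone.
#'
#' @param n_districts Number of districts (default 25).
#' @param seed Integer seed; the map is deterministic given the seed.
#' @param extent Numeric `c(x_min, y_min, x_max, y_max)` in km.
#' @param total_population National population; district populations are
#'   integers that sum to this total exactly.
#' @return An object of class `"district_map"`: a list with
#'   `districts` (data.frame: `id`, `seed_x`, `seed_y`, `climate_zone`,
#'   `population`, `area_km2`), `polygons` (named list of closed x/y
#'   matrices), and `extent`.
#' @examples
#' dm <- generate_districts(25, seed = 1)
#' sum(dm$districts$population)  # exactly the configured total
#' @export
generate_districts <- function(n_districts = 25, seed = 1,
                               extent = c(0, 0, 250, 420),
                               total_population = 22e6) {
  if (n_districts < 2) stop("n_districts must be at least 2")
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2])
  set.seed(seed)
  w <- extent[3] - extent[1]
  h <- extent[4] - extent[2]
  # inhibition sampling keeps seed points apart so no district degenerates
  dmin <- 0.45 * sqrt(w * h / n_districts)
  xs <- ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n_districts && tries < 20000L) {
    cx <- stats::runif(1, extent[1], extent[3])
    cy <- stats::runif(1, extent[2], extent[4])
    if (length(xs) == 0L || min(sqrt((xs - cx)^2 + (ys - cy)^2)) >= dmin) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
    tries <- tries + 1L
  }
  while (length(xs) < n_districts) {  # fallback if inhibition stalls
    xs <- c(xs, stats::runif(1, extent[1], extent[3]))
    ys <- c(ys, stats::runif(1, extent[2], extent[4]))
  }

  dd <- deldir::deldir(xs, ys, rw = c(extent[1], extent[3], extent[2], extent[4]))
  tiles <- deldir::tile.list(dd)
  ids <- sprintf("D%02d", seq_len(n_districts))
  polygons <- lapply(tiles, function(t) {
    m <- cbind(x = t$x, y = t$y)
    rbind(m, m[1, , drop = FALSE])  # close the ring
  })
  names(polygons) <- ids
  area <- vapply(polygons, .polygon_area, numeric(1))

  # dryness gradient: north (high y) and east (high x) are drier, mirroring
  # the island's wet southwest / dry north-and-east zonation
  score <- 0.65 * (ys - extent[2]) / h + 0.35 * (xs - extent[1]) / w
  qs <- stats::quantile(score, c(0.24, 0.52), names = FALSE, type = 1)
  zone <- ifelse(score <= qs[1], "wet",
                 ifelse(score <= qs[2], "intermediate", "dry"))
  if (n_districts >= 3 && length(unique(zone)) < 3) {
    o <- order(score)  # ensure all three zones exist for small maps
    zone[o[1]] <- "wet"; zone[o[ceiling(n_districts / 2)]] <- "intermediate"
    zone[o[n_districts]] <- "dry"
  }

  dens <- c(wet = 8, intermediate = 2.5, dry = 1)[zone]
  popw <- area * dens
  pop <- .allocate_integer_total(popw, total_population)

  districts <- data.frame(
    id = ids, seed_x = xs, seed_y = ys, climate_zone = zone,
    population = pop, area_km2 = as.numeric(area),
    stringsAsFactors = FALSE
  )
  structure(list(districts = districts, polygons = polygons, extent = extent),
            class = "district_map")
}

# shoelace area of a closed ring
.polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# largest-remainder rounding of weights to integers summing to total
.allocate_integer_total <- function(weights, total) {
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  frac <- raw - base
  add <- integer(length(raw))
  if (left > 0) add[order(frac, decreasing = TRUE)[seq_len(left)]] <- 1L
  as.integer(base + add)
}

#' Assign points to districts
#'
#' For maps generated by [generate_districts()] assignment is by nearest
#' Voronoi seed (exact and unambiguous). For maps read from file without
#' seed points, assignment is by point-in-polygon with ties (boundary
#' points) broken towards the lowest district id.
#'
#' @param map A `"district_map"`.
#' @param x,y Numeric coordinate vectors (km).
#' @return Integer vector of row indices into `map$districts` (`NA` when a
#'   point falls outside every polygon).
#' @export
assign_district <- function(map, x, y) {
  stopifnot(inherits(map, "district_map"), length(x) == length(y))
  d <- map$districts
  if (!is.null(d$seed_x) && !anyNA(d$seed_x)) {
    # nearest-seed lookup, vectorised over points
    d2 <- outer(x, d$seed_x, "-")^2 + outer(y, d$seed_y, "-")^2
    return(max.col(-d2, ties.method = "first"))
  }
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nrow(d))) {
    ring <- map$polygons[[d$id[i]]]
    inside <- sp::point.in.polygon(x, y, ring[, 1], ring[, 2]) > 0
    out[is.na(out) & inside] <- i
  }
  out
}
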