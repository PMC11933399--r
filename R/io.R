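#' Read a well-records CSV
#'
#' Expects a header with at least `well_id`, `x`, `y`; `district`,
#' `climate_zone`, `depth` and the index-parameter columns are optional.
#' Empty cells are missing values (never zero). Concentrations are assumed
#' mg/L.
#'
#' @param path CSV path.
#' @return A validated `"well_table"`.
#' @export
read_wells <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("well_id", "x", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  dup <- tab$well_id[duplicated(tab$well_id)]
  if (length(dup) > 0)
    stop("duplicate well_id: ", paste(unique(dup), collapse = ", "))
  for (p in intersect(c(index_parameters(), "depth"), names(tab))) {
    bad <- which(!is.na(tab[[p]]) & tab[[p]] < 0)
    if (length(bad) > 0)
      stop("negative ", p, " at row(s): ", paste(bad, collapse = ", "))
  }
  class(tab) <- c("well_table", "data.frame")
  tab
}

#' @rdname read_wells
#' @param wells A `"well_table"` to write.
#' @export
write_wells <- function(wells, path) {
  utils::write.csv(as.data.frame(wells), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a district map as GeoJSON
#'
#' Polygons are written in the map's planar km coordinate frame; an
#' optional `crs` string is carried opaquely in the top-level object.
#'
#' @param map A `"district_map"`.
#' @param path Output path.
#' @param crs Optional CRS tag (opaque).
#' @export
write_districts <- function(map, path, crs = NULL) {
  d <- map$districts
  features <- lapply(seq_len(nrow(d)), function(i) {
    ring <- map$polygons[[d$id[i]]]
    props <- list(id = d$id[i], climate_zone = d$climate_zone[i],
                  population = d$population[i], area_km2 = d$area_km2[i])
    if (!is.null(d$seed_x)) {
      props$seed_x <- d$seed_x[i]; props$seed_y <- d$seed_y[i]
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  obj <- list(type = "FeatureCollection",
              extent = map$extent, features = features)
  if (!is.null(crs)) obj$crs <- crs
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a district map from GeoJSON
#'
#' @param path GeoJSON FeatureCollection with Polygon features carrying
#'   properties `id`, `population`, `climate_zone`.
#' @return A `"district_map"`.
#' @export
read_districts <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- list(); polygons <- list()
  for (f in obj$features) {
    pr <- f$properties
    if (is.null(pr$id) || is.null(pr$population))
      stop("feature missing id or population property")
    if (pr$population < 0) stop("negative population for district ", pr$id)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    if (f$geometry$type != "Polygon" || nrow(ring) < 4)
      stop("invalid geometry for district ", pr$id)
    if (any(ring[1, ] != ring[nrow(ring), ]))
      stop("unclosed polygon ring for district ", pr$id)
    polygons[[pr$id]] <- ring
    rows[[length(rows) + 1L]] <- data.frame(
      id = pr$id, climate_zone = pr$climate_zone %||% NA_character_,
      population = as.numeric(pr$population),
      seed_x = as.numeric(pr$seed_x %||% NA_real_),
      seed_y = as.numeric(pr$seed_y %||% NA_real_),
      area_km2 = as.numeric(pr$area_km2 %||% .polygon_area(ring)),
      stringsAsFactors = FALSE
    )
  }
  districts <- do.call(rbind, rows)
  extent <- if (!is.null(obj$extent)) unlist(obj$extent) else {
    all_xy <- do.call(rbind, polygons)
    c(min(all_xy[, 1]), min(all_xy[, 2]), max(all_xy[, 1]), max(all_xy[, 2]))
  }
  structure(list(districts = districts, polygons = polygons,
                 extent = as.numeric(extent)),
            class = "district_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read a parameter grid as ESRI ASCII raster
#'
#' Plain-text AAIGrid format: header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) then rows of values from the
#' top row down. Round trip preserves values to better than 1e-9 relative.
#'
#' @param grid A `"parameter_grid"`.
#' @param path Output path.
#' @export
write_grid_ascii <- function(grid, path) {
  s <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols), paste("nrows", s$n_rows),
    paste("xllcorner", format(s$x_min, digits = 15)),
    paste("yllcorner", format(s$y_min, digits = 15)),
    paste("cellsize", format(s$cell_size, digits = 15)),
    "NODATA_value -9999"
  ), con)
  v <- grid$values
  v[is.na(v)] <- -9999
  for (i in seq(s$n_rows, 1L)) # top row first
    writeLines(paste(format(v[i, ], digits = 15, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_grid_ascii
#' @param parameter,method Metadata to attach on read.
#' @export
read_grid_ascii <- function(path, parameter = NA_character_,
                            method = NA_character_) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[[`, "", 2), vapply(hdr, `[[`, "", 1))
  nc <- as.integer(kv[["ncols"]]); nr <- as.integer(kv[["nrows"]])
  cs <- as.numeric(kv[["cellsize"]])
  x0 <- as.numeric(kv[["xllcorner"]]); y0 <- as.numeric(kv[["yllcorner"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  M <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  M <- M[seq(nr, 1L), , drop = FALSE]  # back to south-up row order
  M[M == nodata] <- NA_real_
  structure(list(
    parameter = parameter,
    spec = grid_spec(x0, y0, x0 + nc * cs, y0 + nr * cs, cs),
    values = M, variance = NULL, method = method
  ), class = "parameter_grid")
}

#' Read a station time-series CSV
#'
#' @param path CSV with columns `station`, `date` (ISO 8601),
#'   `parameter`, `value` and optionally `unit`.
#' @return Long data.frame suitable for [to_monthly()] and
#'   [station_matrix()].
#' @export
read_station_series <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("station", "date", "parameter", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tab$date <- as.Date(tab$date)
  if (anyNA(tab$date)) stop("unparseable dates in ", path)
  tab
}
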