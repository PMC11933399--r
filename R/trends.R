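#' Aggregate a station series to calendar months
#'
#' @param series data.frame with columns `date` (Date or ISO-8601 text)
#'   and `value`; other columns (e.g. `station`, `parameter`) are carried
#'   through when constant. Monthly input passes through unchanged.
#' @return data.frame with one row per observed calendar month (`date` =
#'   first of month, `value` = mean of that month's readings). Months with
#'   no observation are absent, i.e. missing — never zero.
#' @export
to_monthly <- function(series) {
  if (nrow(series) == 0L) stop("empty series")
  d <- as.Date(series$date)
  key <- format(d, "%Y-%m")
  out <- data.frame(
    date = as.Date(paste0(sort(unique(key)), "-01")),
    value = as.numeric(tapply(series$value, key, mean, na.rm = TRUE))
  )
  for (col in c("station", "parameter", "unit"))
    if (col %in% names(series) && length(unique(series[[col]])) == 1L)
      out[[col]] <- series[[col]][1]
  out[!is.na(out$value), , drop = FALSE]
}

# decimal years since the first observation
.decimal_year <- function(d) as.numeric(d - d[1]) / 365.25

#' Linear trend of a monthly station series
#'
#' Ordinary least squares of the monthly values on decimal time; the slope
#' is reported in value units per year. Missing months are simply absent
#' from the fit.
#'
#' @param series Monthly data.frame (see [to_monthly()]) with at least 24
#'   monthly values.
#' @return List: `slope` (units/year), `intercept`, `se` (slope standard
#'   error), `n` (months used).
#' @export
linear_trend <- function(series) {
  series <- series[!is.na(series$value), , drop = FALSE]
  if (nrow(series) < 24)
    stop("need at least 24 monthly values for a yearly trend")
  t <- .decimal_year(as.Date(series$date))
  fit <- stats::lm(series$value ~ t)
  co <- summary(fit)$coefficients
  list(slope = unname(co["t", "Estimate"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       se = unname(co["t", "Std. Error"]),
       n = nrow(series))
}

#' Seasonal climatology of a monthly series
#'
#' Mean per calendar month across all years, missing-aware: a calendar
#' month never observed yields `NA`.
#'
#' @param series Monthly data.frame with at least 12 monthly values.
#' @return Named numeric vector of length 12 (Jan..Dec).
#' @export
seasonal_climatology <- function(series) {
  series <- series[!is.na(series$value), , drop = FALSE]
  if (nrow(series) < 12) stop("need at least 12 monthly values")
  m <- as.integer(format(as.Date(series$date), "%m"))
  out <- stats::setNames(rep(NA_real_, 12), month.abb)
  agg <- tapply(series$value, m, mean)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Mean-ordered station x month matrix
#'
#' Builds the heatmap matrix for one parameter: rows are stations sorted
#' by descending station mean (ties broken by station id), columns are
#' every calendar month in the union of the stations' ranges, cells are
#' monthly means with gaps preserved as `NA`.
#'
#' @param series_set Long data.frame with columns `station`, `date`,
#'   `value` and (optionally) `parameter` — which must then be a single
#'   parameter — at any cadence; aggregated to months internally.
#' @return Numeric matrix (stations x months) with dimnames.
#' @export
station_matrix <- function(series_set) {
  if ("parameter" %in% names(series_set) &&
      length(unique(series_set$parameter)) > 1L)
    stop("station_matrix expects a single parameter")
  stations <- sort(unique(series_set$station))
  if (length(stations) < 2) stop("need at least 2 stations")
  monthly <- lapply(stations, function(s)
    to_monthly(series_set[series_set$station == s, , drop = FALSE]))
  names(monthly) <- stations
  all_dates <- sort(unique(do.call(c, lapply(monthly, `[[`, "date"))))
  all_months <- seq(min(all_dates), max(all_dates), by = "month")
  M <- matrix(NA_real_, length(stations), length(all_months),
              dimnames = list(stations, format(all_months, "%Y-%m")))
  for (s in stations) {
    i <- match(monthly[[s]]$date, all_months)
    M[s, i] <- monthly[[s]]$value
  }
  means <- rowMeans(M, na.rm = TRUE)
  M[order(-means, rownames(M)), , drop = FALSE]
}

#' Simulate monitoring-station series
#'
#' Generates monthly series for several stations with station-specific
#' levels and linear trends, a shared 12-month seasonal cycle, Gaussian
#' noise, and optional missing months — the structure of a river
#' water-quality monitoring network.
#'
#' @param n_stations Number of stations.
#' @param n_years Years of monthly data.
#' @param levels Station mean levels (recycled).
#' @param slopes Station trends in units/year (recycled).
#' @param seasonal_amplitude Amplitude of the shared seasonal sinusoid.
#' @param noise_sd Gaussian noise standard deviation.
#' @param missing_rate Fraction of months deleted at random.
#' @param start Start date.
#' @param seed Integer seed.
#' @return Long data.frame: `station`, `date`, `parameter`, `value`,
#'   `unit`.
#' @export
simulate_station_series <- function(n_stations = 12, n_years = 14,
                                    levels = 30, slopes = -2,
                                    seasonal_amplitude = 2, noise_sd = 1,
                                    missing_rate = 0.05,
                                    start = as.Date("2003-01-01"), seed = 1) {
  set.seed(seed)
  months <- seq(start, by = "month", length.out = 12 * n_years)
  t <- as.numeric(months - months[1]) / 365.25
  levels <- rep_len(levels, n_stations)
  slopes <- rep_len(slopes, n_stations)
  season <- seasonal_amplitude * sin(2 * pi * (as.integer(format(months, "%m")) - 1) / 12)
  out <- do.call(rbind, lapply(seq_len(n_stations), function(i) {
    v <- levels[i] + slopes[i] * t + season + stats::rnorm(length(t), 0, noise_sd)
    keep <- stats::runif(length(t)) >= missing_rate
    data.frame(station = sprintf("S%02d", i), date = months[keep],
               parameter = "COD", value = v[keep], unit = "mg/L",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
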