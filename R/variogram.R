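#' Construct a variogram model
#'
#' @param model `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget Non-negative nugget variance.
#' @param sill Total sill (nugget + partial sill), `sill >= nugget`.
#' @param range Range parameter (km), positive. For the exponential and
#'   gaussian models this is the practical-range-style scale parameter of
#'   `1 - exp(-h/range)` and `1 - exp(-(h/range)^2)`.
#' @return A `"variogram_model"`.
#' @export
variogram_model <- function(model = c("spherical", "exponential", "gaussian"),
                            nugget, sill, range) {
  model <- match.arg(model)
  if (nugget < 0 || sill < nugget) stop("need sill >= nugget >= 0")
  if (range <= 0) stop("range must be positive")
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

# semivariance gamma(h); gamma(0) = 0 by convention
vgm_gamma <- function(vm, h) {
  t <- h / vm$range
  g <- switch(vm$model,
    spherical   = ifelse(t < 1, 1.5 * t - 0.5 * t^3, 1),
    exponential = 1 - exp(-t),
    gaussian    = 1 - exp(-t^2)
  )
  ifelse(h > 0, vm$nugget + (vm$sill - vm$nugget) * g, 0)
}

# stationary covariance C(h) = sill - gamma(h); C(0) = sill
vgm_cov <- function(vm, h) vm$sill - vgm_gamma(vm, h)

#' Fit a variogram model to well observations
#'
#' Computes the empirical semivariogram (binned mean of half squared
#' differences of the observed values of `parameter`) and fits the chosen
#' model by weighted least squares (weights proportional to the pair count
#' in each lag bin).
#'
#' @param points A `"well_table"`; rows with missing `parameter` values
#'   are dropped.
#' @param parameter Column to model.
#' @param model Variogram family (default `"spherical"`).
#' @param n_lags Number of lag bins (default 15).
#' @param cutoff Maximum lag distance; default one half of the maximum
#'   pairwise distance.
#' @return A `"variogram_model"` with attributes `empirical` (lag table)
#'   and `degenerate` (`TRUE` when all values are equal, in which case a
#'   zero-sill nugget model is returned).
#' @export
fit_variogram <- function(points, parameter,
                          model = c("spherical", "exponential", "gaussian"),
                          n_lags = 15, cutoff = NULL) {
  model <- match.arg(model)
  ok <- !is.na(points[[parameter]])
  x <- points$x[ok]; y <- points$y[ok]; z <- points[[parameter]][ok]
  n <- length(z)
  if (n < 10) stop("need at least 10 observed points to fit a variogram")
  if (stats::var(z) == 0) {
    vm <- variogram_model(model, 0, 0, range = 1)
    # sill 0 would fail validation; build by hand
    vm$sill <- 0; vm$nugget <- 0
    attr(vm, "degenerate") <- TRUE
    return(vm)
  }
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- 0.5 * as.vector(stats::dist(z))^2
  if (is.null(cutoff)) cutoff <- max(d) / 2
  keep <- d <= cutoff & d > 0
  d <- d[keep]; g <- g[keep]
  bins <- cut(d, breaks = seq(0, cutoff, length.out = n_lags + 1),
              include.lowest = TRUE)
  emp <- data.frame(
    h = as.numeric(tapply(d, bins, mean)),
    gamma = as.numeric(tapply(g, bins, mean)),
    n = as.numeric(tapply(g, bins, length))
  )
  emp <- emp[stats::complete.cases(emp) & emp$n > 0, ]

  s2 <- stats::var(z)
  obj <- function(par) {
    vm <- list(model = model, nugget = par[1], sill = par[1] + par[2],
               range = par[3])
    sum(emp$n * (vgm_gamma(vm, emp$h) - emp$gamma)^2)
  }
  init <- c(max(min(emp$gamma), 1e-6 * s2),
            max(s2 - min(emp$gamma), 1e-6 * s2),
            cutoff / 3)
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(0, 1e-9 * s2, cutoff * 1e-3),
                      upper = c(3 * s2, 4 * s2, 3 * cutoff))
  vm <- variogram_model(model, nugget = fit$par[1],
                        sill = fit$par[1] + fit$par[2], range = fit$par[3])
  attr(vm, "empirical") <- emp
  attr(vm, "degenerate") <- FALSE
  vm
}
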