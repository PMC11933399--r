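# observed, deduplicated point support for one parameter
.krige_points <- function(points, parameter) {
  ok <- !is.na(points[[parameter]])
  x <- points$x[ok]; y <- points$y[ok]; z <- points[[parameter]][ok]
  key <- paste(signif(x, 12), signif(y, 12))
  if (anyDuplicated(key)) {
    warning("duplicate point locations: averaging coincident values")
    z <- as.numeric(tapply(z, key, mean))
    x <- as.numeric(tapply(x, key, function(v) v[1]))
    y <- as.numeric(tapply(y, key, function(v) v[1]))
  }
  list(x = x, y = y, z = z)
}

# augmented ordinary-kriging matrix in semivariance form, with a ridge
# fallback for ill-conditioned systems
.ok_system <- function(vm, x, y) {
  n <- length(x)
  G <- vgm_gamma(vm, as.matrix(stats::dist(cbind(x, y))))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  list(A = A, n = n)
}

.solve_ok <- function(A, b, n) {
  tryCatch(solve(A, b), error = function(e) {
    warning("ill-conditioned kriging system: adding ridge jitter")
    A[seq_len(n), seq_len(n)] <- A[seq_len(n), seq_len(n)] +
      diag(1e-8 * max(abs(A)), n)
    solve(A, b)
  })
}

#' Ordinary kriging onto a grid
#'
#' Predicts `parameter` at every cell centre of `spec` by ordinary kriging
#' with the given variogram: weights solve the semivariance system
#' augmented with the unbiasedness constraint (weights sum to 1). With a
#' zero nugget the predictor is exact at data locations. Predictions are
#' computed through the dual formulation (one linear solve for any number
#' of query points); kriging variances, which require a per-query solve,
#' are computed only when `compute_variance = TRUE`.
#'
#' Right-skewed concentrations may be kriged in log space
#' (`log_transform = TRUE`); back-transformation is `exp(prediction)`
#' (the lognormal median, which preserves threshold exceedance ordering)
#' unless `back_transform = "mean"`, which applies the lognormal mean
#' correction `exp(prediction + variance/2)` and forces variance
#' computation.
#'
#' @param points A `"well_table"` (missing values of `parameter` dropped).
#' @param parameter Column to interpolate.
#' @param variogram A `"variogram_model"`, e.g. from [fit_variogram()].
#' @param spec A `"grid_spec"`.
#' @param log_transform Krige `log(value)` instead of the raw value.
#' @param back_transform `"median"` (default) or `"mean"`; only used with
#'   `log_transform`.
#' @param compute_variance Also return the kriging variance raster.
#' @return A `"parameter_grid"`: `parameter`, `spec`, `values` matrix
#'   (n_rows x n_cols), optional `variance`, `method = "ordinary_kriging"`.
#' @export
krige <- function(points, parameter, variogram, spec,
                  log_transform = FALSE,
                  back_transform = c("median", "mean"),
                  compute_variance = FALSE) {
  back_transform <- match.arg(back_transform)
  if (log_transform && back_transform == "mean") compute_variance <- TRUE
  pts <- .krige_points(points, parameter)
  n <- length(pts$z)
  if (n < 3) stop("ordinary kriging needs at least 3 distinct points")
  z <- if (log_transform) log(pts$z) else pts$z
  sys <- .ok_system(variogram, pts$x, pts$y)
  dual <- .solve_ok(sys$A, c(z, 0), n)
  b <- dual[seq_len(n)]; a <- dual[n + 1]

  ctr <- grid_centers(spec)
  m <- length(ctr$x)
  pred <- numeric(m)
  vrc <- if (compute_variance) numeric(m) else NULL
  chunk <- max(1L, floor(2e6 / n))
  Ainv <- if (compute_variance) solve(sys$A) else NULL
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    D <- sqrt(outer(pts$x, ctr$x[s:e], "-")^2 +
              outer(pts$y, ctr$y[s:e], "-")^2)
    G0 <- vgm_gamma(variogram, D)
    pred[s:e] <- crossprod(G0, b) + a
    if (compute_variance) {
      B <- rbind(G0, 1)
      W <- Ainv %*% B
      vrc[s:e] <- pmax(colSums(W * B), 0)
    }
  }
  if (log_transform) {
    pred <- if (back_transform == "mean") exp(pred + vrc / 2) else exp(pred)
  }
  structure(list(
    parameter = parameter, spec = spec,
    values = matrix(pred, spec$n_rows, spec$n_cols),
    variance = if (compute_variance) matrix(vrc, spec$n_rows, spec$n_cols),
    method = "ordinary_kriging",
    log_transform = log_transform, variogram = variogram, n_points = n
  ), class = "parameter_grid")
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Prediction at a query is the convex combination of the
#' `max_neighbors` nearest observed values with weights
#' `distance^(-power)`; a query coincident with a data point returns that
#' point's value. Used for parameters whose local variation should be
#' preserved rather than smoothed (nitrate, by default routing).
#'
#' @param points A `"well_table"`.
#' @param parameter Column to interpolate.
#' @param power Positive IDW exponent (default 2).
#' @param spec A `"grid_spec"`.
#' @param max_neighbors Neighbours per query (default 12).
#' @return A `"parameter_grid"` with `method = "idw"`.
#' @export
idw <- function(points, parameter, power = 2, spec, max_neighbors = 12) {
  if (power <= 0) stop("power must be positive")
  pts <- .krige_points(points, parameter)
  n <- length(pts$z)
  if (n < 1) stop("idw needs at least 1 observed point")
  k <- min(max_neighbors, n)
  ctr <- grid_centers(spec)
  m <- length(ctr$x)
  pred <- numeric(m)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    D <- sqrt(outer(ctr$x[s:e], pts$x, "-")^2 +
              outer(ctr$y[s:e], pts$y, "-")^2)
    pred[s:e] <- apply(D, 1L, function(d) {
      nn <- order(d)[seq_len(k)]
      dn <- d[nn]
      if (dn[1] < 1e-12) return(mean(pts$z[nn][dn < 1e-12]))
      w <- dn^(-power)
      sum(w * pts$z[nn]) / sum(w)
    })
  }
  structure(list(
    parameter = parameter, spec = spec,
    values = matrix(pred, spec$n_rows, spec$n_cols),
    variance = NULL, method = "idw", power = power,
    max_neighbors = max_neighbors, n_points = n
  ), class = "parameter_grid")
}

#' Leave-one-out standardized RMSE of ordinary kriging
#'
#' Predicts each observed point from all the others under the given
#' variogram, standardizes the residual by the predicted kriging standard
#' deviation, and returns the root mean square of the standardized
#' residuals. Values close to 1 indicate well-calibrated kriging
#' variances. Computed through the covariance-form kriging matrix inverse,
#' so a single factorisation serves all n leave-one-out fits.
#'
#' @param points A `"well_table"`.
#' @param parameter Column to validate.
#' @param variogram A `"variogram_model"` (must have positive sill).
#' @param log_transform Validate in log space.
#' @return Numeric scalar with attribute `"n_skipped"` (points with
#'   non-positive predicted variance, skipped with a warning).
#' @export
loo_standardized_rmse <- function(points, parameter, variogram,
                                  log_transform = FALSE) {
  pts <- .krige_points(points, parameter)
  n <- length(pts$z)
  if (n < 10) stop("need at least 10 points for leave-one-out validation")
  if (variogram$sill <= 0) stop("variogram sill must be positive")
  z <- if (log_transform) log(pts$z) else pts$z
  C <- vgm_cov(variogram, as.matrix(stats::dist(cbind(pts$x, pts$y))))
  diag(C) <- variogram$sill
  K <- rbind(cbind(C, 1), c(rep(1, n), 0))
  Kinv <- tryCatch(solve(K), error = function(e) {
    warning("ill-conditioned kriging system: adding ridge jitter")
    K[seq_len(n), seq_len(n)] <- K[seq_len(n), seq_len(n)] +
      diag(1e-8 * variogram$sill, n)
    solve(K)
  })
  lambda <- as.vector(Kinv %*% c(z, 0))[seq_len(n)]
  q <- diag(Kinv)[seq_len(n)]
  # leave-one-out residual and variance (matrix-inverse identities for
  # kriging cross-validation): e_i = lambda_i / q_i, sigma2_i = 1 / q_i
  ok <- q > 1e-12
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(n_skipped, " point(s) skipped: non-positive predicted variance")
  e <- lambda[ok] / q[ok]
  s2 <- 1 / q[ok]
  structure(sqrt(mean(e^2 / s2)), n_skipped = n_skipped)
}
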