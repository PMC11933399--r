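#' Iterative random-forest imputation of well records
#'
#' Fills missing index-parameter values by chained random-forest
#' regression: missing cells are initialised with column medians, then
#' parameters are visited in order of increasing missingness, each
#' regressed on all other parameters (plus auxiliary predictors such as
#' depth and, optionally, district and climate zone) and its missing cells
#' re-predicted. Iteration stops when the normalised sum of squared
#' changes in the imputed values first increases — the values from the
#' last improving iteration are returned — or after `max_iter` sweeps.
#' Imputation quality is estimated without a hold-out set from each
#' forest's out-of-bag (OOB) mean squared error.
#'
#' @param wells A `"well_table"` with missing values among the index
#'   parameters. Observed cells pass through unchanged.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum sweeps over all parameters (default 10).
#' @param seed Integer seed; results are deterministic given the seed
#'   (forests are grown single-threaded).
#' @param include_categorical Use district and climate zone as predictors
#'   (default `TRUE`).
#' @param parameters Columns to impute; defaults to the index parameters
#'   present in the table.
#' @return An `"rf_imputation"` list: `completed` (well table with no
#'   missing index values), `per_variable_oob` (OOB NRMSE per parameter,
#'   `sqrt(oob_mse / var_observed)`), `overall_oob_nrmse` (root mean of the
#'   per-variable standardized OOB errors), `n_iterations`, `converged`.
#' @export
rf_impute <- function(wells, n_trees = 100, max_iter = 10, seed = 1,
                      include_categorical = TRUE,
                      parameters = intersect(index_parameters(), names(wells))) {
  stopifnot(inherits(wells, "data.frame"), length(parameters) > 0)
  X <- as.data.frame(wells)[parameters]
  n <- nrow(X)
  if (n < 2) stop("need at least 2 rows to impute")
  n_mis <- vapply(X, function(v) sum(is.na(v)), integer(1))
  if (any(n_mis == n))
    stop("parameter(s) with no observed values cannot be imputed: ",
         paste(parameters[n_mis == n], collapse = ", "))
  mask <- is.na(as.matrix(X))

  aux <- list()
  for (a in c("depth", "yield", "gwl_depth"))
    if (a %in% names(wells) && !anyNA(wells[[a]])) aux[[a]] <- wells[[a]]
  if (include_categorical) {
    for (a in c("district", "climate_zone"))
      if (a %in% names(wells)) aux[[a]] <- factor(wells[[a]])
  }
  aux <- as.data.frame(aux, stringsAsFactors = FALSE)

  # median initialisation
  cur <- X
  for (p in parameters)
    cur[[p]][mask[, p]] <- stats::median(X[[p]], na.rm = TRUE)

  if (!any(mask)) {
    class(cur) <- class(wells)
    out_tab <- wells; out_tab[parameters] <- cur
    return(structure(list(completed = out_tab,
                          per_variable_oob = stats::setNames(rep(0, length(parameters)), parameters),
                          overall_oob_nrmse = 0,
                          n_iterations = 0L, converged = TRUE),
                     class = "rf_imputation"))
  }

  visit <- parameters[order(n_mis[parameters])]
  visit <- visit[n_mis[visit] > 0]
  var_obs <- vapply(parameters, function(p) stats::var(X[[p]], na.rm = TRUE),
                    numeric(1))
  oob <- stats::setNames(rep(NA_real_, length(parameters)), parameters)
  prev <- cur
  prev_oob <- oob
  prev_diff <- Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    for (k in seq_along(visit)) {
      p <- visit[k]
      df <- cur[setdiff(parameters, p)]
      if (ncol(aux) > 0) df <- cbind(df, aux)
      y <- cur[[p]]
      obs <- !mask[, p]
      fit <- ranger::ranger(
        x = df[obs, , drop = FALSE], y = X[[p]][obs],
        num.trees = n_trees, num.threads = 1,
        seed = (seed * 131L + it * 17L + k) %% .Machine$integer.max
      )
      oob[p] <- sqrt(fit$prediction.error / var_obs[p])
      y[mask[, p]] <- stats::predict(fit, df[mask[, p], , drop = FALSE],
                                     num.threads = 1)$predictions
      cur[[p]] <- y
    }
    num <- den <- 0
    for (p in visit) {
      num <- num + sum((cur[[p]][mask[, p]] - prev[[p]][mask[, p]])^2)
      den <- den + sum(cur[[p]][mask[, p]]^2)
    }
    diff <- num / den
    if (diff >= prev_diff) {      # degradation: keep previous iteration
      cur <- prev
      oob <- prev_oob
      it <- it - 1L
      converged <- TRUE
      break
    }
    prev <- cur
    prev_oob <- oob
    prev_diff <- diff
  }

  out_tab <- wells
  out_tab[parameters] <- cur
  class(out_tab) <- unique(c("well_table", class(wells)))
  imputed_vars <- names(oob)[!is.na(oob)]
  structure(list(
    completed = out_tab,
    per_variable_oob = oob,
    overall_oob_nrmse = sqrt(mean(oob[imputed_vars]^2)),
    n_iterations = it,
    converged = converged
  ), class = "rf_imputation")
}

#' Column-mean imputation baseline
#'
#' Replaces every missing cell with the mean of its column's observed
#' values — the no-information baseline against which model-based
#' imputation is judged (its NRMSE tends to 1 under MCAR).
#'
#' @param wells A `"well_table"`.
#' @param parameters Columns to fill; defaults to the index parameters
#'   present.
#' @return The completed table.
#' @export
impute_baseline <- function(wells,
                            parameters = intersect(index_parameters(), names(wells))) {
  out <- wells
  for (p in parameters) {
    v <- out[[p]]
    if (all(is.na(v))) stop("column '", p, "' has no observed values")
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    out[[p]] <- v
  }
  out
}

#' Missing-cell mask of a well table
#'
#' @param wells A `"well_table"`.
#' @param parameters Columns to inspect.
#' @return Logical matrix (wells x parameters), `TRUE` where missing.
#' @export
missing_mask <- function(wells,
                         parameters = intersect(index_parameters(), names(wells))) {
  m <- is.na(as.matrix(as.data.frame(wells)[parameters]))
  colnames(m) <- parameters
  m
}

#' Normalised root mean squared imputation error
#'
#' Over the masked (truly missing) cells only:
#' `sqrt(mean((true - imputed)^2) / var(true))`, with the *population*
#' variance (denominator n) of the true masked values, so that a perfect
#' imputation scores 0 and mean imputation of an MCAR column scores about
#' 1. With several parameters, each parameter's squared error is first
#' standardized by its own true-masked variance and the standardized
#' errors are pooled by their mean before the square root, so
#' high-magnitude parameters do not dominate. Per-parameter values are
#' returned alongside.
#'
#' @param true_table Complete ground-truth `"well_table"` (synthetic or
#'   testing context).
#' @param imputed_table The completed table to score.
#' @param mask Logical matrix as from [missing_mask()] (computed on the
#'   degraded table), `TRUE` at imputed cells.
#' @return Numeric scalar, with attribute `"per_parameter"`.
#' @export
nrmse <- function(true_table, imputed_table, mask) {
  params <- colnames(mask)
  if (is.null(params)) stop("mask must have parameter column names")
  if (!any(mask)) stop("mask is empty: no imputed cells to score")
  ratios <- numeric(0)
  per <- stats::setNames(rep(NA_real_, length(params)), params)
  for (p in params) {
    sel <- mask[, p]
    if (!any(sel)) next
    tv <- true_table[[p]][sel]
    iv <- imputed_table[[p]][sel]
    v <- mean((tv - mean(tv))^2)      # population variance
    if (v == 0)
      stop("true values of '", p, "' are constant over the mask; ",
           "NRMSE is undefined")
    r <- mean((tv - iv)^2) / v
    per[p] <- sqrt(r)
    ratios <- c(ratios, r)
  }
  structure(sqrt(mean(ratios)), per_parameter = per)
}
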