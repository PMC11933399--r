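#' WAWQI unit weights
#'
#' Unit weights inversely proportional to the standards:
#' `K = 1 / sum(1 / S_i)` and `W_i = K / S_i`, so the weights sum to 1 and
#' parameters with stricter (smaller) limits weigh more.
#'
#' @param standards A `"standards"` table (all limits positive).
#' @return Named numeric vector of weights summing to 1.
#' @export
unit_weights <- function(standards) {
  s <- standards$limit
  if (any(s <= 0)) stop("all standards must be positive")
  K <- 1 / sum(1 / s)
  stats::setNames(K / s, standards$parameter)
}

#' WAWQI quality rating
#'
#' Sub-index `Q_i = 100 * (V_i - V_o) / (S_i - V_o)` with observed value
#' `V_i`, standard `S_i` and ideal value `V_o` (0 for all concentration
#' parameters; 7.0 would be used for pH were it included). A value at the
#' standard rates 100; ratings above 100 indicate values beyond the
#' standard.
#'
#' @param value Observed concentration(s).
#' @param entry A one-row standards entry.
#' @param ideal Ideal value `V_o` (default 0).
#' @return Numeric rating(s).
#' @export
quality_rating <- function(value, entry, ideal = 0) {
  if (entry$limit == ideal) stop("standard equals ideal value: rating undefined")
  100 * (value - ideal) / (entry$limit - ideal)
}

#' Weighted arithmetic water quality index of one sample
#'
#' `score = sum(W_i * Q_i) / sum(W_i)` over the declared parameter set;
#' with the full index-parameter set the denominator is 1. When a subset
#' of parameters is supplied, the weights are renormalized over that
#' subset.
#'
#' @param values Named numeric vector, parameter -> concentration.
#' @param standards A `"standards"` table.
#' @param ideals Named numeric vector of ideal values, or a single number
#'   recycled (default 0).
#' @return Numeric score (>= 0 for non-negative concentrations).
#' @export
wawqi_score <- function(values, standards, ideals = 0) {
  params <- names(values)
  if (length(params) == 0L) stop("empty parameter set")
  std <- standards[match(params, standards$parameter), ]
  if (anyNA(std$limit)) stop("no standard for: ",
                             paste(params[is.na(std$limit)], collapse = ", "))
  if (length(ideals) == 1L) ideals <- stats::setNames(rep(ideals, length(params)), params)
  w <- unit_weights(std)
  q <- vapply(params, function(p)
    quality_rating(values[[p]], std[std$parameter == p, ], ideals[[p]]),
    numeric(1))
  sum(w * q) / sum(w)
}

#' Classify a WAWQI score
#'
#' Bands: `[0, 25)` excellent, `[25, 50)` good, `[50, 75)` poor,
#' `[75, 100)` very poor, `>= 100` unsuitable for drinking.
#'
#' @param score Non-negative numeric vector.
#' @return Ordered factor.
#' @export
classify_wqi <- function(score) {
  if (any(score < 0)) stop("WQI score cannot be negative")
  cut(score, breaks = c(-Inf, 25, 50, 75, 100, Inf), right = FALSE,
      labels = c("excellent", "good", "poor", "very_poor", "unsuitable"),
      ordered_result = TRUE)
}

#' District-level WAWQI
#'
#' Scores every well with [wawqi_score()] and aggregates to districts as
#' the mean of per-well scores (preserving the influence of hotspot
#' wells); set `aggregate = "mean_concentration"` to instead score the
#' district-mean concentrations.
#'
#' @param wells Completed `"well_table"` (no missing index values) with a
#'   `district` column.
#' @param districts A `"district_map"`.
#' @param standards A `"standards"` table.
#' @param ideals Ideal values (default 0).
#' @param aggregate `"mean_score"` (default) or `"mean_concentration"`.
#' @return data.frame: `district`, `n_wells`, `score`, `class`,
#'   `standards_source`; districts with zero wells are excluded.
#' @export
district_wqi <- function(wells, districts, standards, ideals = 0,
                         aggregate = c("mean_score", "mean_concentration")) {
  aggregate <- match.arg(aggregate)
  if (nrow(wells) == 0L) stop("no wells")
  params <- intersect(index_parameters(), names(wells))
  if (anyNA(wells[params])) stop("missing index values; impute first")
  f <- factor(wells$district, levels = districts$districts$id)
  if (aggregate == "mean_score") {
    well_scores <- apply(as.matrix(as.data.frame(wells)[params]), 1L, function(v)
      wawqi_score(stats::setNames(as.numeric(v), params), standards, ideals))
    score <- tapply(well_scores, f, mean)
  } else {
    score <- tapply(seq_len(nrow(wells)), f, function(i) {
      m <- colMeans(as.data.frame(wells)[i, params, drop = FALSE])
      wawqi_score(m, standards, ideals)
    })
  }
  n_wells <- as.integer(table(f))
  keep <- n_wells > 0L
  data.frame(
    district = districts$districts$id[keep],
    n_wells = n_wells[keep],
    score = as.numeric(score[keep]),
    class = classify_wqi(as.numeric(score[keep])),
    standards_source = standards$source[1],
    stringsAsFactors = FALSE
  )
}
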