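#' The ten index parameters
#'
#' Returns the ordered set of chemical parameters that enter the hazard
#' index and the WAWQI: Chloride, Alkalinity, Nitrate, Nitrite, Fluoride,
#' Phosphate, TDS, Hardness, Iron and Sulphate. pH is screened in many
#' monitoring programmes but is not part of the ten-parameter index.
#'
#' @return Character vector of length 10.
#' @export
index_parameters <- function() {
  c("Chloride", "Alkalinity", "Nitrate", "Nitrite", "Fluoride",
    "Phosphate", "TDS", "Hardness", "Iron", "Sulphate")
}

# Packaged standards table. For Sri Lanka standards printed as a
# highest-desirable / maximum-permissible range, the lower (most
# protective) bound is stored; users may override via load_standards(path=).
.standards_table <- function() {
  p <- index_parameters()
  data.frame(
    parameter = rep(p, 2L),
    limit = c(
      # WHO / US EPA screening limits (mg/L). Alkalinity has no WHO limit;
      # 400 mg/L is the state-level screening value used alongside them.
      250, 400, 10, 1.0, 1.5, 0.1, 600, 500, 0.3, 400,
      # Sri Lanka standards (highest-desirable bound where a range exists)
      200, 400, 10, 0.01, 0.6, 2.0, 500, 250, 1.0, 200
    ),
    unit = "mg/L",
    source = rep(c("WHO_EPA", "SriLanka"), each = length(p)),
    # iron deficiency, not excess, is the health concern
    direction = rep(ifelse(p == "Iron", "below_is_hazard", "above_is_hazard"), 2L),
    stringsAsFactors = FALSE
  )
}

#' Load drinking-water screening standards
#'
#' Returns one standards entry per index parameter: the concentration limit,
#' unit, and hazard direction. All parameters are hazardous above their
#' limit except Iron, for which concentrations *below* the limit are
#' flagged (low dietary iron intake via drinking water is linked to anemia).
#'
#' @param source `"WHO_EPA"` (default, used by the hazard index) or
#'   `"SriLanka"`. Where the national standard is published as a
#'   highest-desirable/maximum-permissible range, the lower (most
#'   protective) bound is used.
#' @param path Optional path to a user CSV with columns
#'   `parameter, limit, unit, source, direction` overriding the packaged
#'   table.
#' @return A data.frame of class `"standards"` with columns `parameter`,
#'   `limit`, `unit`, `source`, `direction`, one row per index parameter.
#' @examples
#' std <- load_standards("WHO_EPA")
#' std[std$parameter == "Chloride", "limit"]  # 250 mg/L
#' @export
load_standards <- function(source = c("WHO_EPA", "SriLanka"), path = NULL) {
  source <- match.arg(source)
  tab <- if (is.null(path)) {
    .standards_table()
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("parameter", "limit", "unit", "source", "direction")
    if (!all(need %in% names(out)))
      stop("standards file must have columns: ", paste(need, collapse = ", "))
    out
  }
  tab <- tab[tab$source == source, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no standards found for source '", source, "'")
  if (any(tab$limit <= 0)) stop("standards limits must be positive")
  bad <- tab$direction == "below_is_hazard" & tab$parameter != "Iron"
  if (any(bad))
    stop("below_is_hazard direction is reserved for Iron: ",
         paste(tab$parameter[bad], collapse = ", "))
  rownames(tab) <- NULL
  class(tab) <- c("standards", "data.frame")
  tab
}

#' Look up one standards entry
#'
#' @param standards A `"standards"` table from [load_standards()].
#' @param parameter Parameter name.
#' @return A one-row standards entry.
#' @export
standards_entry <- function(standards, parameter) {
  i <- which(standards$parameter == parameter)
  if (length(i) != 1L)
    stop("no unique standards entry for parameter '", parameter, "'")
  standards[i, , drop = FALSE]
}

#' Does a concentration violate its screening standard?
#'
#' A value violates when it is strictly above the limit
#' (`above_is_hazard`) or strictly below it (`below_is_hazard`, Iron only).
#' A value exactly at the limit is compliant in both directions.
#'
#' @param value Numeric vector of concentrations (mg/L); must be
#'   non-missing and non-negative — impute or drop missing values first.
#' @param entry A one-row standards entry (see [standards_entry()]).
#' @return Logical vector, `TRUE` where the standard is violated.
#' @export
violates <- function(value, entry) {
  if (anyNA(value))
    stop("missing concentration passed to violates(); impute or drop first")
  if (any(value < 0)) stop("negative concentration passed to violates()")
  if (nrow(entry) != 1L) stop("entry must be a single standards row")
  if (entry$direction == "above_is_hazard") value > entry$limit
  else value < entry$limit
}
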