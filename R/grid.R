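#' Define a regular analysis grid
#'
#' @param x_min,y_min,x_max,y_max Grid bounds in km.
#' @param cell_size Cell edge length in km (default 2, the working
#'   resolution of the interpolated hazard maps).
#' @return A `"grid_spec"`: bounds, `cell_size`, `n_cols`, `n_rows`.
#'   Cell (i, j) has its centre at
#'   `(x_min + (j - 0.5) * cell_size, y_min + (i - 0.5) * cell_size)`.
#' @export
grid_spec <- function(x_min, y_min, x_max, y_max, cell_size = 2) {
  stopifnot(x_max > x_min, y_max > y_min, cell_size > 0)
  structure(list(
    x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
    cell_size = cell_size,
    n_cols = as.integer(ceiling((x_max - x_min) / cell_size)),
    n_rows = as.integer(ceiling((y_max - y_min) / cell_size))
  ), class = "grid_spec")
}

#' @rdname grid_spec
#' @param map A `"district_map"` whose extent the grid should cover.
#' @export
grid_spec_for <- function(map, cell_size = 2) {
  e <- map$extent
  grid_spec(e[1], e[2], e[3], e[4], cell_size)
}

# coordinates of all cell centres, in column-major cell order
# (cell k = (i - 1) + (j - 1) * n_rows + 1, matching as.vector(matrix))
grid_centers <- function(spec) {
  xc <- spec$x_min + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  yc <- spec$y_min + (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  list(x = rep(xc, each = spec$n_rows), y = rep(yc, times = spec$n_cols),
       xc = xc, yc = yc)
}

# map coordinates to (row, col) cell indices, clamped to the grid
grid_cell_of <- function(spec, x, y) {
  j <- pmin(pmax(ceiling((x - spec$x_min) / spec$cell_size), 1L), spec$n_cols)
  i <- pmin(pmax(ceiling((y - spec$y_min) / spec$cell_size), 1L), spec$n_rows)
  list(row = as.integer(i), col = as.integer(j))
}
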