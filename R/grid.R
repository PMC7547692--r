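#' Define a uniform raster grid domain
#'
#' The simulation grid is a regular raster with square cells. Grids are stored
#' as base matrices with row 1 at the southern (bottom) edge and columns
#' increasing eastwards; the origin is the lower-left corner and coordinates
#' refer to cell centres. The flow-path length across a cell (`d_s`) is taken
#' equal to `cell_size`.
#'
#' @param n_rows,n_cols Grid dimensions (each at least 4).
#' @param cell_size Cell edge length in metres (default 2, the resolution of
#'   the terrain data this model is designed around).
#' @param outlet Integer vector `c(row, col)` of the single outlet cell, which
#'   must lie on the grid boundary. Defaults to the middle of the southern
#'   edge.
#' @return An object of class `grid_domain`.
#' @export
grid_domain <- function(n_rows, n_cols, cell_size = 2,
                        outlet = c(1L, max(1L, floor(n_cols / 2)))) {
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 4 || n_cols < 4) {
    stop("invalid domain: n_rows and n_cols must each be >= 4", call. = FALSE)
  }
  if (!is.numeric(cell_size) || cell_size <= 0) {
    stop("invalid domain: cell_size must be > 0", call. = FALSE)
  }
  outlet <- as.integer(outlet)
  if (length(outlet) != 2 || any(is.na(outlet)) ||
      outlet[1] < 1 || outlet[1] > n_rows || outlet[2] < 1 ||
      outlet[2] > n_cols) {
    stop("outlet must be a valid c(row, col) cell", call. = FALSE)
  }
  on_boundary <- outlet[1] %in% c(1L, as.integer(n_rows)) ||
    outlet[2] %in% c(1L, as.integer(n_cols))
  if (!on_boundary) stop("outlet must lie on the grid boundary", call. = FALSE)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), outlet = outlet),
    class = "grid_domain"
  )
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("<grid_domain> %d x %d cells, %.3g m cells, outlet (%d, %d)\n",
              x$n_rows, x$n_cols, x$cell_size, x$outlet[1], x$outlet[2]))
  invisible(x)
}

n_cells <- function(domain) domain$n_rows * domain$n_cols

outlet_index <- function(domain) {
  (domain$outlet[2] - 1L) * domain$n_rows + domain$outlet[1]
}

#' Cell-centre coordinates of every grid cell
#'
#' @param domain A [grid_domain()].
#' @return A data frame with `x`, `y` (metres from the lower-left corner) in
#'   column-major (linear index) order.
#' @export
cell_coordinates <- function(domain) {
  dx <- domain$cell_size
  data.frame(
    x = (rep(seq_len(domain$n_cols), each = domain$n_rows) - 0.5) * dx,
    y = (rep(seq_len(domain$n_rows), times = domain$n_cols) - 0.5) * dx
  )
}

as_grid_matrix <- function(values, domain) {
  matrix(values, nrow = domain$n_rows, ncol = domain$n_cols)
}
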