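#' Nested coarse/fine grid geometry
#'
#' Defines a rectangular fine grid together with the block factor `k` that
#' nests it inside a coarse grid: each coarse cell is a `k` x `k` block of
#' fine cells (partial blocks at the right/bottom edges are valid coarse
#' cells). Fine cells are indexed row-major, 0-based, with site IDs of the
#' form `"r{row}c{col}"`; coarse cells use the same scheme on the coarse
#' grid.
#'
#' @param n_rows_fine,n_cols_fine Fine grid dimensions (positive integers).
#' @param block_factor Fine cells per coarse-cell side (`k >= 1`).
#' @param cell_size_fine Fine cell edge length, informational only.
#' @param origin Coordinates of the center of fine cell (0, 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(50, 50, block_factor = 5)
#' head(fine_site_ids(g))
#' @export
grid_spec <- function(n_rows_fine, n_cols_fine, block_factor,
                      cell_size_fine = 1, origin = c(0, 0)) {
  if (!is_count(n_rows_fine) || !is_count(n_cols_fine))
    stop_validation("grid dimensions must be positive integers")
  if (!is_count(block_factor))
    stop_validation("block_factor must be a positive integer")
  structure(list(
    n_rows_fine = as.integer(n_rows_fine),
    n_cols_fine = as.integer(n_cols_fine),
    block_factor = as.integer(block_factor),
    n_rows_coarse = as.integer(ceiling(n_rows_fine / block_factor)),
    n_cols_coarse = as.integer(ceiling(n_cols_fine / block_factor)),
    cell_size_fine = cell_size_fine,
    origin = origin
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d fine cells, k = %d (%d x %d coarse cells)\n",
              x$n_rows_fine, x$n_cols_fine, x$block_factor,
              x$n_rows_coarse, x$n_cols_coarse))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
n_fine_cells <- function(grid) grid$n_rows_fine * grid$n_cols_fine

#' @rdname grid_spec
#' @export
n_coarse_cells <- function(grid) grid$n_rows_coarse * grid$n_cols_coarse

cell_ids <- function(n_rows, n_cols) {
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  sprintf("r%dc%d", rows, cols)
}

#' Site identifiers of all fine (or coarse) cells, row-major
#' @param grid A `grid_spec`.
#' @export
fine_site_ids <- function(grid) cell_ids(grid$n_rows_fine, grid$n_cols_fine)

#' @rdname fine_site_ids
#' @export
coarse_site_ids <- function(grid) cell_ids(grid$n_rows_coarse, grid$n_cols_coarse)

# 1-based position of the coarse cell containing each fine cell (row-major)
fine_block_index <- function(grid) {
  frow <- rep(seq_len(grid$n_rows_fine) - 1L, each = grid$n_cols_fine)
  fcol <- rep(seq_len(grid$n_cols_fine) - 1L, times = grid$n_rows_fine)
  crow <- frow %/% grid$block_factor
  ccol <- fcol %/% grid$block_factor
  crow * grid$n_cols_coarse + ccol + 1L
}

#' Cell-center coordinates of all fine cells
#'
#' Returns an `n x 2` matrix of (x, y) cell-center coordinates in the grid's
#' length units, row order matching [fine_site_ids()]. Used for the spatially
#' corrected correlation test.
#' @param grid A `grid_spec`.
#' @export
fine_coords <- function(grid) {
  frow <- rep(seq_len(grid$n_rows_fine) - 1L, each = grid$n_cols_fine)
  fcol <- rep(seq_len(grid$n_cols_fine) - 1L, times = grid$n_rows_fine)
  cbind(x = grid$origin[1] + fcol * grid$cell_size_fine,
        y = grid$origin[2] + frow * grid$cell_size_fine)
}
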