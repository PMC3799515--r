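#' Define a shared raster grid geometry
#'
#' All rasters, unit maps and point locations in one analysis share a single
#' grid geometry: a planar rectangle split into square cells. Cell `(1, 1)` is
#' the **top-left** cell (raster convention); row indices increase southward,
#' column indices increase eastward. Coordinates are in projected map units
#' (the default cell size of 100 corresponds to 100 m pixels).
#'
#' @param n_rows,n_cols Positive integers, the grid dimensions.
#' @param cell_size Cell edge length in map units. Default 100.
#' @param origin_x,origin_y Planar coordinates of the lower-left corner of the
#'   grid extent. Default 0.
#'
#' @return An object of class `rcmc_grid`.
#' @examples
#' g <- grid_geometry(20, 20)
#' cell_centers(g)
#' @export
grid_geometry <- function(n_rows, n_cols, cell_size = 100,
                          origin_x = 0, origin_y = 0) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1, length(cell_size) == 1)
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols)) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  if (!is.finite(cell_size) || cell_size <= 0) {
    abort("`cell_size` must be a positive length in map units.")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.double(cell_size),
      origin_x = as.double(origin_x), origin_y = as.double(origin_y)
    ),
    class = "rcmc_grid"
  )
}

#' @export
print.rcmc_grid <- function(x, ...) {
  cat(sprintf(
    "<rcmc_grid> %d x %d cells of %g map units, origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y
  ))
  invisible(x)
}

grid_extent <- function(grid) {
  c(
    xmin = grid$origin_x, xmax = grid$origin_x + grid$n_cols * grid$cell_size,
    ymin = grid$origin_y, ymax = grid$origin_y + grid$n_rows * grid$cell_size
  )
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid An [grid_geometry()] object.
#' @param cell_row,cell_col Optional vectors of cell indices; if omitted, all
#'   cells are returned in column-major order.
#' @return A tibble with columns `cell_row`, `cell_col`, `x`, `y`.
#' @export
cell_centers <- function(grid, cell_row = NULL, cell_col = NULL) {
  if (is.null(cell_row)) {
    cell_row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
    cell_col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  }
  tibble(
    cell_row = as.integer(cell_row), cell_col = as.integer(cell_col),
    x = grid$origin_x + (as.double(cell_col) - 0.5) * grid$cell_size,
    y = grid$origin_y + (grid$n_rows - as.double(cell_row) + 0.5) * grid$cell_size
  )
}

# map-coordinate -> cell index; points outside the extent get NA
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$cell_size)
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(cell_row = as.integer(row), cell_col = as.integer(col))
}

#' Construct a raster on a grid geometry
#'
#' Thin S3 wrapper used for background-population weights, intensity surfaces,
#' p-value surfaces and hot-spot masks: a numeric matrix (`n_rows` x `n_cols`,
#' row 1 = north edge) plus the shared [grid_geometry()] and a label.
#'
#' @param values Numeric matrix of dimension `n_rows` x `n_cols` (or a single
#'   value, recycled).
#' @param grid The shared [grid_geometry()].
#' @param label A short label, e.g. a stratum name, `"combined"`, `"p"`.
#' @return An `rcmc_raster` object.
#' @export
rcmc_raster <- function(values, grid, label = "") {
  if (length(values) == 1) {
    values <- matrix(as.double(values), grid$n_rows, grid$n_cols)
  }
  if (!is.matrix(values) || nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    abort("`values` must be an n_rows x n_cols matrix matching the grid.")
  }
  structure(
    list(values = values, grid = grid, label = as.character(label)),
    class = "rcmc_raster"
  )
}

#' @export
print.rcmc_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<rcmc_raster '%s'> %d x %d | finite cells: %d | range [%g, %g]\n",
    x$label, x$grid$n_rows, x$grid$n_cols, length(v),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
  invisible(x)
}

#' Tidy a raster into a cell-level tibble
#'
#' @param x An `rcmc_raster`.
#' @param ... Unused.
#' @return A tibble with `cell_row`, `cell_col`, `x`, `y`, `value`.
#' @export
as_tibble.rcmc_raster <- function(x, ...) {
  out <- cell_centers(x$grid)
  out$value <- as.vector(x$values)
  out
}

#' @export
autoplot.rcmc_raster <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(
      fill = object$label, x = "easting", y = "northing",
      title = sprintf("%s surface", object$label)
    )
}
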