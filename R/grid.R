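#' Define a regular analysis grid
#'
#' The analysis operates on a regular grid of square cells in a projected
#' plane (units: metres). Cells are indexed row-major from the origin corner;
#' the centre of cell \code{(i, j)} (1-based row, column) sits at
#' \code{origin + ((j - 0.5), (i - 0.5)) * cell_size}.
#'
#' @param n_rows,n_cols Number of rows and columns (positive integers).
#' @param cell_size Cell edge length in metres. The default of 5000 m gives
#'   the 5 km x 5 km squares used for national mapping.
#' @param origin_x,origin_y Coordinates of the grid's lower-left corner.
#' @return An object of class \code{grid_spec}.
#' @examples
#' g <- grid_spec(10, 10)
#' head(cell_centers(g))
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 5000, origin_x = 0, origin_y = 0) {
  stopifnot(is.numeric(n_rows), is.numeric(n_cols), length(n_rows) == 1L,
            length(n_cols) == 1L)
  if (n_rows < 1 || n_cols < 1 || n_rows != round(n_rows) || n_cols != round(n_cols))
    stop("n_rows and n_cols must be positive integers")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (origin %g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Cell centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A two-column matrix (x, y) with one row per cell, in row-major
#'   cell order (row 1 column 1, row 1 column 2, ...).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  i <- rep(seq_len(grid$n_rows), each = grid$n_cols)   # row index
  j <- rep(seq_len(grid$n_cols), times = grid$n_rows)  # column index
  cbind(x = grid$origin_x + (j - 0.5) * grid$cell_size,
        y = grid$origin_y + (i - 0.5) * grid$cell_size)
}

#' Locate points on a grid
#'
#' Maps planar coordinates to row-major cell indices. Points outside the
#' grid's bounding box get \code{NA}.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors.
#' @return Integer vector of row-major cell indices (or \code{NA}).
#' @export
cell_index_at <- function(grid, x, y) {
  stopifnot(inherits(grid, "grid_spec"), length(x) == length(y))
  j <- floor((x - grid$origin_x) / grid$cell_size) + 1
  i <- floor((y - grid$origin_y) / grid$cell_size) + 1
  # points exactly on the top/right boundary belong to the last cell
  j[x == grid$origin_x + grid$n_cols * grid$cell_size] <- grid$n_cols
  i[y == grid$origin_y + grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- i < 1 | i > grid$n_rows | j < 1 | j > grid$n_cols | !is.finite(x) | !is.finite(y)
  idx <- (i - 1L) * grid$n_cols + j
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Construct a raster layer on a grid
#'
#' A \code{set_raster} is a single layer of per-cell values co-registered
#' with a [grid_spec()]. Values are stored in row-major cell order.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric vector of length \code{n_rows * n_cols}, or a single
#'   value to recycle.
#' @param name Optional layer name.
#' @return An object of class \code{set_raster}.
#' @export
set_raster <- function(grid, values, name = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  nc <- n_cells(grid)
  if (length(values) == 1L) values <- rep(as.numeric(values), nc)
  if (length(values) != nc)
    stop(sprintf("values has length %d but the grid has %d cells", length(values), nc))
  structure(list(grid = grid, values = as.numeric(values), name = name),
            class = "set_raster")
}

#' @export
print.set_raster <- function(x, ...) {
  cat(sprintf("<set_raster>%s %d x %d cells of %g m; range [%g, %g]\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.set_raster <- function(x, ...) {
  matrix(x$values, nrow = x$grid$n_rows, ncol = x$grid$n_cols, byrow = TRUE)
}

#' Plot a raster layer
#'
#' @param x A [set_raster()].
#' @param main Plot title (defaults to the layer name).
#' @param ... Passed to [graphics::image()].
#' @export
plot.set_raster <- function(x, main = x$name, ...) {
  g <- x$grid
  xs <- g$origin_x + (seq_len(g$n_cols) - 0.5) * g$cell_size
  ys <- g$origin_y + (seq_len(g$n_rows) - 0.5) * g$cell_size
  graphics::image(xs, ys, t(as.matrix(x)), xlab = "x (m)", ylab = "y (m)",
                  main = if (is.null(main)) "" else main,
                  col = grDevices::hcl.colors(64, "viridis"), useRaster = TRUE, ...)
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  isTRUE(all.equal(a$n_rows, b$n_rows)) && isTRUE(all.equal(a$n_cols, b$n_cols)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol
}

check_registered <- function(grid, ..., what = "raster") {
  for (r in list(...)) {
    if (!inherits(r, "set_raster")) stop(what, " must be a set_raster")
    if (!same_grid(grid, r$grid)) stop(what, " is not co-registered with the analysis grid")
  }
  invisible(TRUE)
}

#' Stack of co-registered covariate layers
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric per-cell vectors (row-major), or of
#'   [set_raster()] objects on the same grid.
#' @param standardization Optional per-layer data frame of means/sds recorded
#'   when layers were standardised (see [generate_covariate_rasters()]).
#' @return An object of class \code{covariate_stack}.
#' @export
covariate_stack <- function(grid, layers, standardization = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be a named list")
  vals <- lapply(names(layers), function(nm) {
    l <- layers[[nm]]
    if (inherits(l, "set_raster")) {
      check_registered(grid, l, what = nm)
      l <- l$values
    }
    if (length(l) != n_cells(grid))
      stop(sprintf("layer '%s' has length %d, expected %d", nm, length(l), n_cells(grid)))
    as.numeric(l)
  })
  names(vals) <- names(layers)
  structure(list(grid = grid, layers = vals, standardization = standardization),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layer(s) [%s] on %d x %d grid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}
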