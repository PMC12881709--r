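#' Grid specification for a planar km raster
#'
#' Defines a regular grid of square cells on a planar kilometre coordinate
#' system (e.g., a national grid with units converted to km).  Cell centres
#' lie at \code{origin + (col - 0.5, row - 0.5) * cell_km}, with row 1 the
#' southernmost row.
#'
#' @param nrows,ncols Number of rows and columns (each at least 2).
#' @param cell_km Cell side length in km (positive).
#' @param origin Numeric length-2: (x, y) of the lower-left corner in km.
#' @return An object of class \code{grid_spec}.
#' @export
grid_spec <- function(nrows, ncols, cell_km = 1, origin = c(0, 0)) {
  stopifnot(nrows >= 2, ncols >= 2, cell_km > 0, length(origin) == 2)
  structure(
    list(nrows = as.integer(nrows), ncols = as.integer(ncols),
         cell_km = as.numeric(cell_km), origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_km, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A \code{grid_spec}.
#' @return A two-column matrix (x_km, y_km), one row per cell in column-major
#'   raster order (row index varies fastest, matching matrix storage).
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  xs <- grid$origin[1] + (seq_len(grid$ncols) - 0.5) * grid$cell_km
  ys <- grid$origin[2] + (seq_len(grid$nrows) - 0.5) * grid$cell_km
  cbind(x_km = rep(xs, each = grid$nrows), y_km = rep(ys, times = grid$ncols))
}

#' Construct a named raster layer
#'
#' A raster is a real-valued matrix bound to a \code{grid_spec}.  Row i,
#' column j of \code{values} is the cell in the i-th row from the south and
#' the j-th column from the west.
#'
#' @param grid A \code{grid_spec}.
#' @param values Numeric matrix \code{nrows x ncols} (recycled if scalar).
#' @param name Layer label.
#' @param units Free-text unit string.
#' @return An object of class \code{pest_raster}.
#' @export
raster_layer <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L) values <- matrix(values, grid$nrows, grid$ncols)
  values <- as.matrix(values)
  dimnames(values) <- NULL
  if (!all(dim(values) == c(grid$nrows, grid$ncols)))
    stop("values shape does not match grid (", grid$nrows, " x ", grid$ncols, ")")
  structure(list(grid = grid, values = values, name = name, units = units),
            class = "pest_raster")
}

#' @export
print.pest_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<pest_raster> '%s' %d x %d @ %g km; range [%.4g, %.4g]%s\n",
              x$name, x$grid$nrows, x$grid$ncols, x$grid$cell_km,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (nzchar(x$units)) paste0(" ", x$units) else ""))
  invisible(x)
}

#' @export
as.matrix.pest_raster <- function(x, ...) x$values

#' Extract raster values as a vector in cell order
#'
#' @param x A \code{pest_raster}.
#' @return Numeric vector in the same column-major order as
#'   \code{\link{cell_centers}}.
#' @export
raster_values <- function(x) {
  stopifnot(inherits(x, "pest_raster"))
  as.vector(x$values)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a$grid), unclass(b$grid)))
}

#' Write / read a raster as plain-text CSV
#'
#' The text format stores the grid header as comment lines followed by the
#' value matrix, so layers round-trip without any binary dependency.
#'
#' @param x A \code{pest_raster}.
#' @param path File path.
#' @return \code{read_raster_csv} returns a \code{pest_raster};
#'   \code{write_raster_csv} returns \code{path} invisibly.
#' @export
write_raster_csv <- function(x, path) {
  stopifnot(inherits(x, "pest_raster"))
  g <- x$grid
  hdr <- c(
    sprintf("# name: %s", x$name),
    sprintf("# units: %s", x$units),
    sprintf("# nrows: %d", g$nrows),
    sprintf("# ncols: %d", g$ncols),
    sprintf("# cell_km: %.17g", g$cell_km),
    sprintf("# origin: %.17g %.17g", g$origin[1], g$origin[2])
  )
  writeLines(hdr, path)
  utils::write.table(x$values, path, append = TRUE, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 6L)
  get <- function(key) sub(sprintf("^# %s: ?", key), "", grep(sprintf("^# %s:", key), hdr, value = TRUE))
  org <- as.numeric(strsplit(get("origin"), " ")[[1]])
  g <- grid_spec(as.integer(get("nrows")), as.integer(get("ncols")),
                 as.numeric(get("cell_km")), org)
  vals <- as.matrix(utils::read.table(path, sep = ",", skip = 6L, header = FALSE))
  dimnames(vals) <- NULL
  raster_layer(g, vals, name = get("name"), units = get("units"))
}
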