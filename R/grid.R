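#' Regular raster grid
#'
#' The shared raster container used by every stage of the pipeline: land-cover
#' classes, moving-window covariates, habitat suitability, resistance and
#' current density all live in `scape_grid` objects. Values are stored as a
#' numeric matrix with row 1 the *southernmost* row (y increases with row
#' index), so all internal math is Cartesian y-up; file readers/writers flip
#' to the north-first convention of the ESRI ASCII format.
#'
#' Cells are half-open squares `[x0 + (j-1)s, x0 + j s)` so a point on a
#' shared boundary belongs to exactly one cell. All coordinates are projected
#' meters.
#'
#' @param values numeric matrix, row 1 = southernmost row.
#' @param cellsize cell edge length in meters (> 0).
#' @param xll,yll x and y coordinate of the lower-left corner of the grid.
#' @param nodata sentinel value marking missing cells (default -9999).
#' @param crs opaque CRS tag carried through unchanged.
#' @return A `scape_grid` object.
#' @export
scape_grid <- function(values, cellsize, xll = 0, yll = 0,
                       nodata = -9999, crs = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("cellsize must be a single positive number (meters)")
  storage.mode(values) <- "double"
  structure(
    list(values = values, cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata), crs = as.character(crs)),
    class = "scape_grid")
}

#' @export
is.scape_grid <- function(x) inherits(x, "scape_grid")

#' @export
dim.scape_grid <- function(x) dim(x$values)

#' @export
print.scape_grid <- function(x, ...) {
  v <- grid_values(x)
  cat(sprintf("<scape_grid> %d rows x %d cols, cellsize %g m\n",
              nrow(x$values), ncol(x$values), x$cellsize))
  cat(sprintf("  origin (lower-left): (%g, %g); nodata %g\n",
              x$xll, x$yll, x$nodata))
  if (any(is.finite(v)))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' Grid values with nodata as NA
#'
#' @param g a `scape_grid`.
#' @return numeric matrix with nodata cells replaced by `NA`.
#' @export
grid_values <- function(g) {
  v <- g$values
  v[v == g$nodata] <- NA_real_
  v
}

#' Replace the value matrix of a grid, keeping its geometry
#'
#' `NA`s in `values` are written back as the grid's nodata sentinel.
#'
#' @param g a `scape_grid` supplying geometry.
#' @param values replacement matrix of identical shape.
#' @export
grid_like <- function(g, values) {
  if (!all(dim(values) == dim(g$values)))
    stop("replacement values must match grid shape")
  values[is.na(values)] <- g$nodata
  scape_grid(values, g$cellsize, g$xll, g$yll, g$nodata, g$crs)
}

#' Check two grids share geometry
#'
#' Grids combined arithmetically (or compared cell-by-cell) must agree in
#' shape, cell size and origin; mismatches are a hard error, never silent
#' resampling.
#'
#' @param a,b `scape_grid` objects.
#' @export
check_same_geometry <- function(a, b) {
  stopifnot(is.scape_grid(a), is.scape_grid(b))
  if (!all(dim(a$values) == dim(b$values)))
    stop("grid geometry mismatch: shapes differ")
  if (abs(a$cellsize - b$cellsize) > 1e-9)
    stop("grid geometry mismatch: cell sizes differ")
  if (abs(a$xll - b$xll) > 1e-6 || abs(a$yll - b$yll) > 1e-6)
    stop("grid geometry mismatch: origins differ")
  invisible(TRUE)
}

#' Cell centers of a grid
#'
#' @param g a `scape_grid`.
#' @return list with vectors `x` (length ncol) and `y` (length nrow) of cell
#'   center coordinates; `y[1]` is the southernmost row center.
#' @export
cell_centers <- function(g) {
  s <- g$cellsize
  list(x = g$xll + (seq_len(ncol(g$values)) - 0.5) * s,
       y = g$yll + (seq_len(nrow(g$values)) - 0.5) * s)
}

#' Map point coordinates to cell row/column indices
#'
#' Uses half-open cell membership, so points on the eastern/northern edge of
#' the grid fall outside it.
#'
#' @param g a `scape_grid`.
#' @param x,y point coordinates (meters).
#' @return data.frame with `row`, `col` (NA for points outside the grid).
#' @export
cell_index <- function(g, x, y) {
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- floor((y - g$yll) / g$cellsize) + 1
  bad <- col < 1 | col > ncol(g$values) | row < 1 | row > nrow(g$values) |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @param g a `scape_grid`.
#' @param x,y coordinates.
#' @return numeric vector (NA outside the grid or at nodata cells).
#' @export
extract_at <- function(g, x, y) {
  idx <- cell_index(g, x, y)
  v <- grid_values(g)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- v[cbind(idx$row[ok], idx$col[ok])]
  out
}
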