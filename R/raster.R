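#' Lightweight single-band raster
#'
#' A minimal in-memory raster: a numeric matrix of cell values plus a planar
#' geotransform. Row 1 is the top of the grid and y increases downward from
#' the upper-left origin (image convention); cell centers are offset half a
#' cell from the grid edges. `NA` marks nodata.
#'
#' @param values numeric matrix of cell values (rows top to bottom).
#' @param origin_x,origin_y planar coordinates (m) of the grid's upper-left
#'   corner.
#' @param cell_size edge length of a square cell (m), > 0.
#' @return An object of class `tex_raster`.
#' @export
tex_raster <- function(values, origin_x = 0, origin_y = 0, cell_size = 1) {
  if (!is.matrix(values) || length(values) == 0L)
    stop("`values` must be a non-empty matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  storage.mode(values) <- "double"
  structure(
    list(values = values,
         origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size)),
    class = "tex_raster")
}

#' @export
print.tex_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<tex_raster> %d x %d cells, %.6g m cell size\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (%.6g, %.6g), extent %.6g x %.6g m\n",
              x$origin_x, x$origin_y,
              ncol(v) * x$cell_size, nrow(v) * x$cell_size))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values [%.6g, %.6g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

is_tex_raster <- function(x) inherits(x, "tex_raster")

#' Cell-center coordinates of a raster
#'
#' @param raster a [tex_raster].
#' @return `cell_centers_x` gives the x coordinate of each column's centers;
#'   `cell_centers_y` the y coordinate of each row's centers (y downward).
#' @export
cell_centers_x <- function(raster) {
  raster$origin_x + (seq_len(ncol(raster$values)) - 0.5) * raster$cell_size
}

#' @rdname cell_centers_x
#' @export
cell_centers_y <- function(raster) {
  raster$origin_y + (seq_len(nrow(raster$values)) - 0.5) * raster$cell_size
}

#' Locate the cell containing a planar point
#'
#' @param raster a [tex_raster].
#' @param x,y planar coordinates (m).
#' @return integer vector `c(row, col)`; errors if outside the extent.
#' @export
point_to_cell <- function(raster, x, y) {
  col <- floor((x - raster$origin_x) / raster$cell_size) + 1L
  row <- floor((y - raster$origin_y) / raster$cell_size) + 1L
  if (any(row < 1L | row > nrow(raster$values) |
          col < 1L | col > ncol(raster$values)))
    stop("point outside raster extent")
  c(as.integer(row), as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows of values, northernmost row
#' first). Because this package's y axis points downward while the format's
#' northing points up, the stored `yllcorner` is `-(origin_y + nrows *
#' cellsize)`; round-trips through these two functions are exact.
#'
#' @param raster a [tex_raster].
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @return `write_asc` returns `path` invisibly; `read_asc` a [tex_raster].
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  stopifnot(is_tex_raster(raster))
  v <- raster$values
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin_x),
    sprintf("yllcorner %.10g", -(raster$origin_y + nrow(v) * raster$cell_size)),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(format(row, digits = 15L,
                                                  trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]])
  nrows <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrows * ncols) stop("corrupt ASCII grid body")
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  tex_raster(m,
             origin_x = vals[["xllcorner"]],
             origin_y = -(vals[["yllcorner"]] + nrows * vals[["cellsize"]]),
             cell_size = vals[["cellsize"]])
}

#' Reflect-pad a matrix
#'
#' Mirror reflection padding by `k` cells on every side, without repeating
#' the edge cell (the row just inside the border is mirrored out), so
#' locally periodic patterns stay periodic across the pad. Used so
#' moving-window statistics cover the full grid.
#'
#' @param m a matrix.
#' @param k pad width in cells (`<= dim(m) - 1`).
#' @export
pad_reflect <- function(m, k) {
  if (k == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (k > nr - 1L || k > nc - 1L) stop("padding exceeds matrix size")
  ri <- c((k + 1L):2L, 1:nr, (nr - 1L):(nr - k))
  ci <- c((k + 1L):2L, 1:nc, (nc - 1L):(nc - k))
  m[ri, ci, drop = FALSE]
}
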