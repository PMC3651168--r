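#' Pixels within a fixed radius of a sample point
#'
#' Membership rule: a pixel belongs to the zone iff its center lies within
#' Euclidean distance `radius` of the point (no fractional-area weighting).
#'
#' @param raster a [tex_raster].
#' @param x,y planar point coordinates (m), inside the raster extent.
#' @param radius buffer radius (m), >= 0.
#' @return data.frame with columns `row`, `col`, `value`, `dist` for every
#'   pixel (valid or nodata) whose center is within the buffer.
#' @export
pixels_in_radius <- function(raster, x, y, radius) {
  stopifnot(is_tex_raster(raster))
  if (radius < 0) stop("`radius` must be >= 0")
  point_to_cell(raster, x, y)  # errors when the point is outside the extent
  cs <- raster$cell_size
  xs <- cell_centers_x(raster)
  ys <- cell_centers_y(raster)
  # candidate rows/cols limited to the bounding square of the buffer
  ci <- which(abs(xs - x) <= radius + cs)
  ri <- which(abs(ys - y) <= radius + cs)
  if (!length(ci) || !length(ri))
    return(data.frame(row = integer(), col = integer(),
                      value = numeric(), dist = numeric()))
  d2 <- outer((ys[ri] - y)^2, (xs[ci] - x)^2, `+`)
  keep <- which(d2 <= radius^2, arr.ind = TRUE)
  data.frame(row = ri[keep[, 1L]],
             col = ci[keep[, 2L]],
             value = raster$values[cbind(ri[keep[, 1L]], ci[keep[, 2L]])],
             dist = sqrt(d2[keep]))
}

#' Zonal mean and standard deviation around sample points
#'
#' Summarizes a raster in a fixed-radius circle around each point: mean and
#' sample standard deviation (divisor n - 1) of the valid pixels whose
#' centers fall inside the buffer. Nodata pixels are excluded from both the
#' count and the moments; a buffer with no valid pixel is returned as a
#' flagged record with `NA` statistics.
#'
#' @param raster a [tex_raster].
#' @param points data.frame with columns `point_id`, `x`, `y`.
#' @param radius buffer radius (m).
#' @param label raster label copied into the output.
#' @return data.frame: `point_id`, `raster`, `radius_m`, `n`, `mean`, `sd`.
#' @export
zonal_summary <- function(raster, points, radius, label = "raster") {
  stopifnot(is_tex_raster(raster), all(c("point_id", "x", "y") %in% names(points)))
  res <- lapply(seq_len(nrow(points)), function(i) {
    px <- pixels_in_radius(raster, points$x[i], points$y[i], radius)
    v <- px$value[!is.na(px$value)]
    n <- length(v)
    data.frame(point_id = points$point_id[i], raster = label,
               radius_m = radius, n = n,
               mean = if (n) mean(v) else NA_real_,
               sd = if (n > 1L) stats::sd(v) else if (n == 1L) 0 else NA_real_)
  })
  do.call(rbind, res)
}
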