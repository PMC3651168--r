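# Sliding-window (box) sums via summed-area tables. Output has one cell per
# fully contained wr x wc window: dims (nrow - wr + 1) x (ncol - wc + 1).
col_cumsum <- function(m) matrix(apply(m, 2L, cumsum), nrow = nrow(m))

box_sum <- function(m, wr, wc) {
  nr <- nrow(m); nc <- ncol(m)
  if (wr > nr || wc > nc) stop("window larger than matrix")
  cs <- rbind(numeric(nc), col_cumsum(m))
  v <- cs[(wr + 1L):(nr + 1L), , drop = FALSE] -
    cs[1L:(nr - wr + 1L), , drop = FALSE]
  cs2 <- cbind(numeric(nrow(v)), t(col_cumsum(t(v))))
  cs2[, (wc + 1L):(nc + 1L), drop = FALSE] -
    cs2[, 1L:(nc - wc + 1L), drop = FALSE]
}

check_window <- function(window, values) {
  if (length(window) != 1L || window < 3L || window %% 2L != 1L)
    stop("`window` must be an odd integer >= 3")
  if (window > min(dim(values)))
    stop("`window` exceeds the raster dimensions")
  as.integer(window)
}

# Shared setup for the focal statistics: reflect-pads (policy "reflect") or
# leaves the grid as-is (policy "mask", NA within half a window of the edge).
focal_prep <- function(raster, window, edge_policy) {
  edge_policy <- match.arg(edge_policy, c("reflect", "mask"))
  v <- raster$values
  w <- check_window(window, v)
  h <- (w - 1L) %/% 2L
  M <- if (edge_policy == "reflect") pad_reflect(v, h) else v
  list(M = M, w = w, h = h, policy = edge_policy,
       out_dim = dim(v), center_na = is.na(v))
}

# Place the sliding-window core back onto the full grid, masking edge cells
# under the "mask" policy and propagating nodata at nodata centers.
focal_finish <- function(core, prep, raster) {
  out <- matrix(NA_real_, prep$out_dim[1L], prep$out_dim[2L])
  if (prep$policy == "reflect") {
    out[] <- core
  } else {
    out[(prep$h + 1L):(prep$out_dim[1L] - prep$h),
        (prep$h + 1L):(prep$out_dim[2L] - prep$h)] <- core
  }
  out[prep$center_na] <- NA_real_
  tex_raster(out, raster$origin_x, raster$origin_y, raster$cell_size)
}

#' Normalized Difference Vegetation Index
#'
#' Per-pixel `(NIR - Red) / (NIR + Red)` from two co-registered single-band
#' rasters; a greenness/productivity proxy in `[-1, 1]`. Pixels where
#' `NIR + Red == 0`, or where either band is nodata, become nodata.
#'
#' @param red,nir [tex_raster] objects with identical geometry.
#' @return a [tex_raster] of NDVI values.
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot(is_tex_raster(red), is_tex_raster(nir))
  if (!same_geometry(red, nir))
    stop("red and NIR bands differ in shape or geotransform")
  s <- nir$values + red$values
  out <- (nir$values - red$values) / s
  out[!is.na(s) & s == 0] <- NA_real_
  tex_raster(out, red$origin_x, red$origin_y, red$cell_size)
}

#' Linear min-max gray-level quantization
#'
#' Bins valid pixel values into `levels` equal-width intervals over the
#' observed range, yielding integer levels `0 .. levels - 1`; the maximum
#' maps to `levels - 1` and nodata propagates. A constant raster maps
#' entirely to level 0 (degenerate range, documented rather than an error).
#'
#' @param raster a [tex_raster].
#' @param levels number of gray levels, >= 2.
#' @return a [tex_raster] of integer-valued levels.
#' @export
quantize <- function(raster, levels) {
  stopifnot(is_tex_raster(raster))
  if (length(levels) != 1L || levels < 2L) stop("`levels` must be >= 2")
  v <- raster$values
  if (all(is.na(v))) stop("raster has no valid pixels")
  rng <- range(v, na.rm = TRUE)
  out <- if (rng[2] == rng[1]) {
    v * 0
  } else {
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1L)
  }
  tex_raster(out, raster$origin_x, raster$origin_y, raster$cell_size)
}

#' First-order focal variance
#'
#' Population variance (divisor n) of the raw pixel values in a `window` x
#' `window` moving box, written to the central cell. With nodata inside a
#' window, n is the number of valid pixels; windows with no valid pixel, and
#' nodata centers, yield nodata.
#'
#' @param raster a [tex_raster].
#' @param window odd window side length in pixels (>= 3).
#' @param edge_policy `"reflect"` (symmetric padding, output covers the whole
#'   grid) or `"mask"` (NA within half a window of the border).
#' @return a [tex_raster] of variances (>= 0).
#' @export
focal_variance <- function(raster, window, edge_policy = "reflect") {
  stopifnot(is_tex_raster(raster))
  p <- focal_prep(raster, window, edge_policy)
  # center on the global mean so the summed-area tables stay well conditioned
  mu <- mean(p$M, na.rm = TRUE)
  valid <- !is.na(p$M)
  x <- ifelse(valid, p$M - mu, 0)
  n <- box_sum(valid + 0, p$w, p$w)
  s1 <- box_sum(x, p$w, p$w)
  s2 <- box_sum(x * x, p$w, p$w)
  m <- s1 / n
  core <- pmax(s2 / n - m * m, 0)
  core[n == 0] <- NA_real_
  focal_finish(core, p, raster)
}

#' First-order focal entropy
#'
#' Shannon entropy (natural log, nats) of the gray-level frequencies inside
#' each moving window: `-sum p_k ln p_k`, bounded by
#' `ln(min(levels, window^2))`. The raster is min-max quantized to `levels`
#' first unless `pre_quantized = TRUE` (then values must already be integers
#' in `0 .. levels - 1`).
#'
#' @inheritParams focal_variance
#' @param levels number of gray levels (>= 2).
#' @param pre_quantized set when the input already holds integer levels.
#' @return a [tex_raster] of entropies in nats.
#' @export
focal_entropy <- function(raster, window, levels = 64L,
                          edge_policy = "reflect", pre_quantized = FALSE) {
  stopifnot(is_tex_raster(raster))
  if (levels < 2L) stop("`levels` must be >= 2")
  q <- if (pre_quantized) raster else quantize(raster, levels)
  check_levels(q$values, levels)
  p <- focal_prep(q, window, edge_policy)
  valid <- !is.na(p$M)
  n <- box_sum(valid + 0, p$w, p$w)
  H <- matrix(0, nrow(n), ncol(n))
  for (k in seq_len(levels) - 1L) {
    ck <- box_sum((valid & !is.na(p$M) & p$M == k) + 0, p$w, p$w)
    pk <- ck / n
    pos <- which(pk > 0)
    H[pos] <- H[pos] - pk[pos] * log(pk[pos])
  }
  H[n == 0] <- NA_real_
  focal_finish(H, p, raster)
}

check_levels <- function(v, levels) {
  ok <- v[!is.na(v)]
  if (length(ok) && (any(ok != floor(ok)) || min(ok) < 0 || max(ok) > levels - 1))
    stop("pre-quantized input must hold integers in 0 .. levels - 1")
}

#' Second-order (co-occurrence) focal contrast
#'
#' Gray-level co-occurrence contrast `sum_ij p(i,j) (i - j)^2` per moving
#' window, with symmetric pair accumulation, averaged over the configured
#' pixel offsets. Computed on quantized levels; `(i - j)^2` is symmetric, so
#' the symmetric-accumulation value equals the single-direction normalized
#' mean squared level difference over all pixel pairs at each offset.
#'
#' Pairs with either endpoint nodata are dropped; a window with no valid pair
#' at any offset yields nodata.
#'
#' @inheritParams focal_entropy
#' @param offsets list of integer `c(row, col)` displacements; the default is
#'   the symmetric 4-direction average at distance 1.
#' @return a [tex_raster] of contrast values (>= 0, 0 iff the window is
#'   constant).
#' @export
glcm_contrast <- function(raster, window, levels = 64L,
                          offsets = list(c(0L, 1L), c(1L, 0L),
                                         c(1L, 1L), c(1L, -1L)),
                          edge_policy = "reflect", pre_quantized = FALSE) {
  stopifnot(is_tex_raster(raster))
  if (!length(offsets)) stop("`offsets` must be non-empty")
  q <- if (pre_quantized) raster else quantize(raster, levels)
  check_levels(q$values, levels)
  p <- focal_prep(q, window, edge_policy)
  M <- p$M; w <- p$w
  valid <- !is.na(M)
  nr <- nrow(M); nc <- ncol(M)
  out_r <- nr - w + 1L; out_c <- nc - w + 1L
  acc <- matrix(0, out_r, out_c)
  nof <- matrix(0, out_r, out_c)
  for (off in offsets) {
    dr <- as.integer(off[1L]); dc <- as.integer(off[2L])
    if (abs(dr) >= w || abs(dc) >= w)
      stop("offset exceeds the window span")
    if (dr == 0L && dc == 0L) stop("null offset not allowed")
    # squared level difference at every first-endpoint position where the
    # shifted second endpoint stays on the grid; zero-filled elsewhere
    r1 <- max(1L, 1L - dr):(nr - max(0L, dr))
    c1 <- max(1L, 1L - dc):(nc - max(0L, dc))
    D <- matrix(0, nr, nc); PV <- matrix(0, nr, nc)
    a <- M[r1, c1, drop = FALSE]
    b <- M[r1 + dr, c1 + dc, drop = FALSE]
    pv <- valid[r1, c1, drop = FALSE] & valid[r1 + dr, c1 + dc, drop = FALSE]
    d <- (a - b)^2
    d[!pv] <- 0
    D[r1, c1] <- d
    PV[r1, c1] <- pv + 0
    # pairs fully inside a w x w window form a (w-|dr|) x (w-|dc|) box of
    # first endpoints anchored max(0,-dr)/max(0,-dc) inside the window
    bs <- box_sum(D, w - abs(dr), w - abs(dc))
    bn <- box_sum(PV, w - abs(dr), w - abs(dc))
    ri <- max(0L, -dr) + seq_len(out_r)
    ci <- max(0L, -dc) + seq_len(out_c)
    s <- bs[ri, ci, drop = FALSE]
    npair <- bn[ri, ci, drop = FALSE]
    has <- npair > 0
    acc[has] <- acc[has] + s[has] / npair[has]
    nof <- nof + has
  }
  core <- acc / nof
  core[nof == 0] <- NA_real_
  focal_finish(core, p, raster)
}
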