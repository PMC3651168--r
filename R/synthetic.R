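#' @importFrom stats rnorm rpois runif rmultinom quantile dnorm qnorm
NULL

HABITATS <- c("grassland", "savanna", "woodland")

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Separable Gaussian smoothing with reflect padding (kernel truncated at
# 3 sd, or at the matrix size for small grids).
gaussian_smooth <- function(m, sd_px) {
  k <- max(1L, ceiling(3 * sd_px))
  k <- min(k, nrow(m) - 1L, ncol(m) - 1L)
  kern <- dnorm(-k:k, sd = sd_px)
  kern <- kern / sum(kern)
  p <- pad_reflect(m, k)
  f <- stats::filter(p, kern, sides = 2)              # columns
  f <- t(stats::filter(t(f), kern, sides = 2))        # rows
  matrix(f, nrow(p), ncol(p))[(k + 1):(k + nrow(m)),
                              (k + 1):(k + ncol(m)), drop = FALSE]
}

#' Ground-truth configuration for the synthetic landscape
#'
#' Bundles every parameter the generators draw from, so recovery experiments
#' know the truth they should recover. Defaults emulate the study system: a
#' three-habitat mosaic (25% grassland / 35% savanna / 40% woodland); a
#' bright, smooth grassland, savanna as bright background dotted with sparse
#' dark tree crowns (high local contrast), and woodland as dense, dark,
#' overlapping crowns; per-year half-normal detection scales chosen so the
#' average detectability in a 100-m point count is roughly 0.51 / 0.48 /
#' 0.33 across the three survey years; and a quadratic richness model
#' (7.08, 0.40, -0.0021) with residual noise sd 4.8.
#'
#' @param fractions habitat area fractions (grassland, savanna, woodland),
#'   summing to 1.
#' @param reflectance per-habitat rendering parameters (see defaults).
#' @param detection_sigma half-normal detection scale per survey year (m).
#' @param density_model intercept/slope/quadratic of the true density (birds
#'   per hectare) as a function of a named per-point covariate.
#' @param richness_model intercept/linear/quadratic richness coefficients
#'   and Gaussian noise sd.
#' @param foliage per-habitat 30-cm-band occupancy weights and mean hits per
#'   profile, tuned so habitat-mean foliage-height diversity is close to
#'   0.53 / 1.51 / 2.70.
#' @param seed default random seed recorded with the configuration.
#' @return a list of class `truth_config`.
#' @export
truth_config <- function(fractions = c(0.25, 0.35, 0.40),
                         reflectance = NULL,
                         detection_sigma = c(57, 54, 42),
                         density_model = list(intercept = 9.22, slope = -0.36,
                                              quadratic = 0,
                                              covariate = "contrast_sd"),
                         richness_model = list(coefficients = c(7.08, 0.40, -0.0021),
                                               noise_sd = 4.8),
                         foliage = NULL,
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("habitat fractions must sum to 1")
  if (any(detection_sigma <= 0)) stop("detection sigma must be > 0")
  if (richness_model$noise_sd < 0) stop("noise sd must be >= 0")
  if (is.null(reflectance)) {
    reflectance <- list(
      # fine grain (1 m, single band, 8-bit-like digital numbers)
      fine_background = c(grassland = 185, savanna = 170, woodland = 95),
      crown_value = 60,
      crown_cover = c(grassland = 0.02, savanna = 0.28, woodland = 0.70),
      crown_scale_m = 4,
      fine_noise_sd = c(grassland = 4, savanna = 5, woodland = 6),
      # coarse grain (30 m, red + NIR digital numbers)
      red_mean = c(grassland = 70, savanna = 55, woodland = 35),
      nir_mean = c(grassland = 110, savanna = 125, woodland = 150),
      coarse_trend_sd = 8, coarse_trend_scale_m = 300,
      coarse_noise_sd = 3)
  }
  if (is.null(foliage)) {
    foliage <- list(
      band_weights = list(
        grassland = c(0.837, 0.126, 0.037),
        savanna = 0.545^(0:11),
        woodland = 0.88^(0:17)),
      hits_per_profile = c(grassland = 12, savanna = 10, woodland = 14),
      n_bands = 40L)
  }
  structure(list(fractions = fractions, reflectance = reflectance,
                 detection_sigma = detection_sigma,
                 density_model = density_model,
                 richness_model = richness_model,
                 foliage = foliage, seed = seed),
            class = "truth_config")
}

#' Generate a patchy three-habitat mosaic
#'
#' Thresholds smoothed Gaussian noise at the quantiles that match the
#' requested area fractions, giving contiguous patches whose characteristic
#' size is set by `patch_scale`. Class labels are integers 1..3 =
#' grassland, savanna, woodland. Because thresholds are empirical quantiles
#' of the realized field, class shares match the request to within one cell.
#'
#' @param extent_m `c(width, height)` of the landscape (m).
#' @param cell_size cell size (m).
#' @param fractions area fractions (grassland, savanna, woodland), sum 1.
#' @param patch_scale Gaussian correlation scale of the mosaic (m), must
#'   exceed `cell_size`.
#' @param seed random seed.
#' @return a [tex_raster] of integer class labels with attribute `habitats`.
#' @export
generate_habitat_map <- function(extent_m = c(2000, 2000), cell_size = 10,
                                 fractions = c(0.25, 0.35, 0.40),
                                 patch_scale = 300, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (patch_scale <= cell_size) stop("patch_scale must exceed cell_size")
  nc <- round(extent_m[1] / cell_size)
  nr <- round(extent_m[2] / cell_size)
  if (nr < 3L || nc < 3L) stop("degenerate extent: fewer than 3x3 cells")
  with_seed(seed, {
    z <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc),
                         sd_px = patch_scale / cell_size)
    br <- quantile(z, cumsum(fractions)[1:2], names = FALSE)
    cls <- matrix(1 + findInterval(z, br, left.open = TRUE), nr, nc)
    out <- tex_raster(cls, 0, 0, cell_size)
    attr(out, "habitats") <- HABITATS
    out
  })
}

habitat_names <- function(map) HABITATS[map$values]

resample_nearest <- function(raster, new_cell) {
  sc <- raster$cell_size / new_cell
  # cover at least the source extent (the last row/col may extend past it)
  nr <- ceiling(nrow(raster$values) * sc - 1e-9)
  nc <- ceiling(ncol(raster$values) * sc - 1e-9)
  ri <- pmin(nrow(raster$values), floor((seq_len(nr) - 0.5) / sc) + 1L)
  ci <- pmin(ncol(raster$values), floor((seq_len(nc) - 0.5) / sc) + 1L)
  tex_raster(raster$values[ri, ci, drop = FALSE],
             raster$origin_x, raster$origin_y, new_cell)
}

#' Render reflectance imagery over a habitat mosaic
#'
#' Produces the two image sources the analysis uses. At the fine grain
#' (default 1 m, one band) each habitat gets a background digital number,
#' tree crowns are carved out of a smoothed random field thresholded at the
#' habitat's canopy-cover fraction (sparse dark crowns on a bright savanna
#' background; dense overlapping crowns in woodland), and Gaussian sensor
#' noise is added. The savanna's bright/dark mix at crown scale makes its
#' local first-order variance exceed both uniform grassland and
#' mostly-closed woodland. At the coarse grain (default 30 m) red and NIR
#' bands are rendered from per-habitat means plus a shared smooth
#' within-habitat trend (entering red negatively and NIR positively, so
#' NDVI varies smoothly within habitats) plus noise.
#'
#' @param map habitat map from [generate_habitat_map()].
#' @param grain `"fine"` (single band) or `"coarse"` (red + NIR).
#' @param params a [truth_config()].
#' @param seed random seed.
#' @param cell_size rendered cell size (m); defaults 1 (fine) / 30 (coarse).
#' @return fine: a [tex_raster]; coarse: `list(red = , nir = )`.
#' @export
render_reflectance <- function(map, grain = c("fine", "coarse"),
                               params = truth_config(), seed = 1L,
                               cell_size = NULL) {
  grain <- match.arg(grain)
  if (any(!map$values %in% 1:3)) stop("unknown habitat label in map")
  rf <- params$reflectance
  if (is.null(cell_size)) cell_size <- if (grain == "fine") 1 else 30
  hm <- resample_nearest(map, cell_size)
  cls <- hm$values
  nr <- nrow(cls); nc <- ncol(cls)
  with_seed(seed, {
    if (grain == "fine") {
      v <- rf$fine_background[cls]
      cover <- rf$crown_cover[cls]
      if (any(cover > 0)) {
        z <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc),
                             sd_px = max(1, rf$crown_scale_m / cell_size))
        z <- (z - mean(z)) / stats::sd(z)
        crown <- z < qnorm(pmin(pmax(cover, 0), 1))
        v[crown] <- rf$crown_value
      }
      noise_sd <- rf$fine_noise_sd[cls]
      v <- v + rnorm(nr * nc, sd = noise_sd)
      tex_raster(matrix(v, nr, nc), map$origin_x, map$origin_y, cell_size)
    } else {
      trend <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc),
                               sd_px = max(1, rf$coarse_trend_scale_m / cell_size))
      trend <- (trend - mean(trend)) / stats::sd(trend) * rf$coarse_trend_sd
      red <- rf$red_mean[cls] - 0.5 * trend + rnorm(nr * nc, sd = rf$coarse_noise_sd)
      nir <- rf$nir_mean[cls] + trend + rnorm(nr * nc, sd = rf$coarse_noise_sd)
      list(red = tex_raster(matrix(pmax(red, 1), nr, nc),
                            map$origin_x, map$origin_y, cell_size),
           nir = tex_raster(matrix(pmax(nir, 1), nr, nc),
                            map$origin_x, map$origin_y, cell_size))
    }
  })
}

#' Place constrained sample points on a habitat map
#'
#' Emulates the field design: random candidate points thinned so that (a)
#' every retained pair is at least `min_sep` apart, (b) no retained point
#' lies within `exclusion_radius` of a masked pixel (roads and other
#' structures that contaminate texture), and (c) every retained point is at
#' least `edge_buffer` from the nearest pixel center of a different habitat
#' class. Candidates are screened in order, greedily.
#'
#' @param map habitat map from [generate_habitat_map()].
#' @param n_candidates number of random candidates.
#' @param min_sep minimum pairwise separation (m).
#' @param exclusion_mask optional [tex_raster]; cells with value > 0 are
#'   excluded features.
#' @param exclusion_radius clearance around masked pixels (m).
#' @param edge_buffer minimum distance to a different habitat class (m).
#' @param seed random seed.
#' @return data.frame `point_id`, `x`, `y`, `habitat` (possibly empty, with
#'   a warning).
#' @export
place_sample_points <- function(map, n_candidates = 400, min_sep = 300,
                                exclusion_mask = NULL, exclusion_radius = 150,
                                edge_buffer = 100, seed = 1L) {
  if (min_sep < 0 || exclusion_radius < 0 || edge_buffer < 0)
    stop("separations and radii must be >= 0")
  cs <- map$cell_size
  nr <- nrow(map$values); nc <- ncol(map$values)
  xs <- cell_centers_x(map); ys <- cell_centers_y(map)
  excl <- NULL
  if (!is.null(exclusion_mask)) {
    idx <- which(!is.na(exclusion_mask$values) & exclusion_mask$values > 0,
                 arr.ind = TRUE)
    excl <- cbind(cell_centers_x(exclusion_mask)[idx[, 2L]],
                  cell_centers_y(exclusion_mask)[idx[, 1L]])
  }
  with_seed(seed, {
    cx <- runif(n_candidates, map$origin_x, map$origin_x + nc * cs)
    cy <- runif(n_candidates, map$origin_y, map$origin_y + nr * cs)
    keep_x <- numeric(); keep_y <- numeric(); keep_h <- integer()
    for (i in seq_len(n_candidates)) {
      row <- min(nr, floor((cy[i] - map$origin_y) / cs) + 1L)
      col <- min(nc, floor((cx[i] - map$origin_x) / cs) + 1L)
      cls <- map$values[row, col]
      if (length(keep_x) &&
          min((keep_x - cx[i])^2 + (keep_y - cy[i])^2) < min_sep^2) next
      if (!is.null(excl) && nrow(excl) &&
          min((excl[, 1L] - cx[i])^2 + (excl[, 2L] - cy[i])^2) <
            exclusion_radius^2) next
      if (edge_buffer > 0 &&
          other_class_within(map, xs, ys, cx[i], cy[i], cls, edge_buffer)) next
      keep_x <- c(keep_x, cx[i]); keep_y <- c(keep_y, cy[i])
      keep_h <- c(keep_h, cls)
    }
    if (!length(keep_x)) warning("no sample point satisfied the constraints")
    data.frame(point_id = if (length(keep_x))
                 sprintf("pt%03d", seq_along(keep_x)) else character(),
               x = keep_x, y = keep_y,
               habitat = HABITATS[keep_h],
               stringsAsFactors = FALSE)
  })
}

# Is any pixel center of a different class within `buffer` of (x, y)?
other_class_within <- function(map, xs, ys, x, y, cls, buffer) {
  ci <- which(abs(xs - x) <= buffer)
  ri <- which(abs(ys - y) <= buffer)
  if (!length(ci) || !length(ri)) return(FALSE)
  sub <- map$values[ri, ci, drop = FALSE]
  other <- which(sub != cls, arr.ind = TRUE)
  if (!nrow(other)) return(FALSE)
  d2 <- (ys[ri[other[, 1L]]] - y)^2 + (xs[ci[other[, 2L]]] - x)^2
  any(d2 <= buffer^2)
}

#' Simulate foliage-height profiles at sample points
#'
#' Sixteen profiles per point (4 sub-plots x 4 directions). Each profile's
#' total hit count is Poisson with a habitat-specific mean and the hits are
#' spread over 30-cm height bands by a habitat-specific multinomial whose
#' weights are tuned so the habitat-mean foliage-height diversity computed
#' by [foliage_height_diversity()] is close to 0.53 (grassland), 1.51
#' (savanna) and 2.70 (woodland).
#'
#' @param points data.frame from [place_sample_points()].
#' @param params a [truth_config()].
#' @param seed random seed.
#' @return long data.frame: `point_id`, `subplot`, `direction`,
#'   `band_1 .. band_K`.
#' @export
simulate_foliage_profiles <- function(points, params = truth_config(),
                                      seed = 1L) {
  fo <- params$foliage
  K <- fo$n_bands
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(points)), function(i) {
      h <- points$habitat[i]
      w <- fo$band_weights[[h]]
      p <- c(w, rep(0, K - length(w)))
      p <- p / sum(p)
      tot <- rpois(16L, fo$hits_per_profile[[h]])
      hits <- t(vapply(tot, function(n) {
        if (n == 0) integer(K) else as.integer(rmultinom(1L, n, p))
      }, integer(K)))
      colnames(hits) <- paste0("band_", seq_len(K))
      cbind(data.frame(point_id = points$point_id[i],
                       subplot = rep(1:4, each = 4L),
                       direction = rep(1:4, times = 4L),
                       stringsAsFactors = FALSE),
            as.data.frame(hits))
    })
    do.call(rbind, rows)
  })
}

#' Simulate multi-year variable-radius point-count surveys
#'
#' True density at a point is `lambda = max(0, b0 + b1 x [+ b2 x^2])` birds
#' per hectare on the supplied covariate. Per visit, the number of birds in
#' the 100-m disc is Poisson(`lambda` x disc area), birds are placed
#' uniformly in the disc, and each is detected independently with
#' half-normal probability `exp(-d^2 / (2 sigma_year^2))`. Only detected
#' birds are returned, carrying their true radial distances.
#'
#' @param points data.frame from [place_sample_points()].
#' @param covariate numeric vector, one value per point.
#' @param truth a [truth_config()]; `detection_sigma` supplies one
#'   half-normal scale per year.
#' @param years number of survey years.
#' @param visits visits per year (recycled to `years`).
#' @param truncation count radius w (m).
#' @param species species code attached to the records.
#' @param seed random seed.
#' @return data.frame `point_id`, `year`, `visit`, `species`, `distance`.
#' @export
simulate_bird_surveys <- function(points, covariate, truth = truth_config(),
                                  years = 3L, visits = c(4L, 4L, 3L),
                                  truncation = 100, species = "GRSP",
                                  seed = 1L) {
  stopifnot(length(covariate) == nrow(points))
  sig <- rep_len(truth$detection_sigma, years)
  if (any(sig <= 0)) stop("detection sigma must be > 0")
  visits <- rep_len(visits, years)
  dm <- truth$density_model
  b2 <- if (is.null(dm$quadratic)) 0 else dm$quadratic
  lambda <- pmax(0, dm$intercept + dm$slope * covariate + b2 * covariate^2)
  area_ha <- pi * truncation^2 / 1e4
  with_seed(seed, {
    out <- list()
    for (y in seq_len(years)) for (v in seq_len(visits[y])) {
      n <- rpois(nrow(points), lambda * area_ha)
      idx <- rep(seq_len(nrow(points)), n)
      if (!length(idx)) next
      d <- truncation * sqrt(runif(length(idx)))
      det <- runif(length(idx)) < exp(-d^2 / (2 * sig[y]^2))
      if (!any(det)) next
      out[[length(out) + 1L]] <- data.frame(
        point_id = points$point_id[idx[det]], year = y, visit = v,
        species = species, distance = d[det], stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(point_id = character(), year = integer(),
                        visit = integer(), species = character(),
                        distance = numeric(), stringsAsFactors = FALSE))
    do.call(rbind, out)
  })
}

#' Simulate per-point species richness
#'
#' `richness = round(max(0, b0 + b1 x + b2 x^2 + Gaussian noise))` on the
#' supplied covariate — the generating model mirrors the quadratic
#' richness-vs-texture relationship the analysis fits.
#'
#' @param points data.frame of sample points (used for its row count/ids).
#' @param covariate numeric vector, one value per point.
#' @param coefficients `c(intercept, linear, quadratic)`.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param seed random seed.
#' @return data.frame `point_id`, `richness` (non-negative integers).
#' @export
simulate_richness <- function(points, covariate,
                              coefficients = c(7.08, 0.40, -0.0021),
                              noise_sd = 4.8, seed = 1L) {
  stopifnot(length(covariate) == nrow(points))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  co <- c(coefficients, 0, 0)[1:3]
  with_seed(seed, {
    mu <- co[1] + co[2] * covariate + co[3] * covariate^2
    r <- round(pmax(0, mu + rnorm(length(covariate), sd = noise_sd)))
    data.frame(point_id = points$point_id, richness = as.integer(r),
               stringsAsFactors = FALSE)
  })
}
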