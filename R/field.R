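#' Foliage-height diversity of one sample point
#'
#' Pools vegetation "hits" across the point's 16 foliage-height profiles
#' (4 sub-plots x 4 cardinal directions) per 30-cm height band and returns
#' the Shannon diversity `-sum p_i ln p_i` (natural log, nats) of the pooled
#' band distribution. Pooling before the index — rather than averaging 16
#' per-profile indices — treats the 16 profiles as one vertical sample of
#' the plot.
#'
#' @param profiles matrix or data.frame of hit counts, one row per profile,
#'   one column per 30-cm band (bands 1..40 covering 0-12 m); exactly 16 rows.
#' @return FHD in nats, or `NA` (with a warning) when no hits were recorded.
#' @export
foliage_height_diversity <- function(profiles) {
  h <- as_profile_matrix(profiles)
  band <- colSums(h)
  tot <- sum(band)
  if (tot < 1) {
    warning("zero total hits: foliage-height diversity undefined")
    return(NA_real_)
  }
  p <- band[band > 0] / tot
  -sum(p * log(p))
}

#' Horizontal vegetation structure of one sample point
#'
#' Canopy height of a profile is the upper edge of its highest band with at
#' least one hit (0 m for an empty profile); the index is the sample
#' standard deviation (divisor n - 1) of the 16 canopy heights, in meters.
#'
#' @inheritParams foliage_height_diversity
#' @param band_height height of one band (m); 0.3 for 30-cm bands.
#' @return horizontal vegetation structure (m, >= 0).
#' @export
horizontal_structure <- function(profiles, band_height = 0.3) {
  h <- as_profile_matrix(profiles)
  heights <- apply(h, 1L, function(row) {
    occ <- which(row > 0)
    if (length(occ)) max(occ) * band_height else 0
  })
  stats::sd(heights)
}

as_profile_matrix <- function(profiles) {
  h <- as.matrix(profiles)
  if (nrow(h) != 16L)
    stop("expected exactly 16 foliage-height profiles per sample point")
  if (any(h < 0) || any(h != floor(h)))
    stop("hit counts must be non-negative integers")
  storage.mode(h) <- "double"
  h
}

#' Vegetation-structure indices for a profile table
#'
#' Computes foliage-height diversity and horizontal vegetation structure for
#' every sample point in a long-format profile table (the field-data layout:
#' one row per profile, hit counts in `band_1 .. band_40`).
#'
#' @param profile_table data.frame with columns `point_id`, `subplot`,
#'   `direction`, and `band_1 .. band_K`.
#' @return data.frame: `point_id`, `fhd`, `hvs`.
#' @export
structure_indices <- function(profile_table) {
  bands <- grep("^band_", names(profile_table), value = TRUE)
  if (!length(bands)) stop("no band_* columns found")
  ids <- unique(profile_table$point_id)
  out <- lapply(ids, function(id) {
    h <- profile_table[profile_table$point_id == id, bands, drop = FALSE]
    data.frame(point_id = id,
               fhd = suppressWarnings(foliage_height_diversity(h)),
               hvs = horizontal_structure(h))
  })
  do.call(rbind, out)
}
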