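#' @importFrom utils write.csv
NULL

# Desk-scale study design: the full study area is emulated on a 2 km x 2 km
# landscape, so the field design's 300-m point separation is scaled to
# 100 m (and the 100-m edge buffer to 50 m) to accommodate ~172 points.
# The fixed covariate scalings align the synthetic zonal texture summaries
# with the covariate units the published prediction equations expect
# (richness quadratic peaks near covariate 95; density stays positive below
# covariate ~25); both were set once from the generator's design.
PIPELINE_DEFAULTS <- list(
  extent_m = c(2000, 2000), habitat_cell = 10, fine_cell = 1,
  n_candidates = 800, min_sep = 100, edge_buffer = 50,
  richness_window = 15L, contrast_window = 51L,
  zonal_radius = 100, richness_cov_scale = 0.125, density_cov_scale = 0.4)

#' Does a texture predictor beat a pure-noise predictor?
#'
#' One end-to-end recovery replicate: simulate a landscape, render the fine
#' image, compute moving-window first-order variance, summarize its
#' standard deviation in 100-m buffers at constrained sample points,
#' simulate richness from that covariate under the quadratic truth, then
#' fit the quadratic regression against (a) the texture covariate and (b) a
#' pure-noise predictor with matched moments.
#'
#' @param seed random seed for the replicate.
#' @param extent_m landscape extent (m).
#' @param window texture window (pixels).
#' @return named vector: adjusted R^2 for `texture` and `noise`, and the
#'   number of sample points `n`.
#' @export
texture_noise_experiment <- function(seed, extent_m = c(2000, 2000),
                                     window = 15L) {
  pd <- PIPELINE_DEFAULTS
  cfg <- truth_config(seed = seed)
  map <- generate_habitat_map(extent_m, pd$habitat_cell,
                              fractions = cfg$fractions, seed = seed)
  fine <- render_reflectance(map, "fine", cfg, seed = seed + 1L)
  tex <- focal_variance(fine, window)
  pts <- place_sample_points(map, n_candidates = pd$n_candidates,
                             min_sep = pd$min_sep,
                             edge_buffer = pd$edge_buffer, seed = seed + 2L)
  zs <- zonal_summary(tex, pts, pd$zonal_radius, "texture")
  cov <- zs$sd * pd$richness_cov_scale
  rich <- simulate_richness(pts, cov,
                            coefficients = cfg$richness_model$coefficients,
                            noise_sd = cfg$richness_model$noise_sd,
                            seed = seed + 3L)
  noise_cov <- with_seed(seed + 4L,
                         rnorm(length(cov), mean(cov), stats::sd(cov)))
  sp <- model_spec("richness", "texture_sd", quadratic = TRUE)
  m_tex <- fit_habitat_model(rich$richness, cov, sp)
  m_noise <- fit_habitat_model(rich$richness, noise_cov, sp)
  c(texture = m_tex$adj_r_squared, noise = m_noise$adj_r_squared,
    n = nrow(pts))
}

#' Simulate a multi-species community for richness analyses
#'
#' Each point holds `richness` species drawn from a habitat-specific pool
#' with geometric rank weights; every held species is detected per visit
#' with a fixed probability. Supplies the survey-event incidence structure
#' that the accumulation curves summarize (no distances attached).
#'
#' @param points data.frame from [place_sample_points()].
#' @param richness per-point species counts.
#' @param years,visits survey design.
#' @param pool_size species pool per habitat.
#' @param p_detect per-visit detection probability of a held species.
#' @param seed random seed.
#' @return data.frame `point_id`, `year`, `visit`, `species`, `distance`.
#' @export
simulate_community_observations <- function(points, richness, years = 3L,
                                            visits = c(4L, 4L, 3L),
                                            pool_size = 40L, p_detect = 0.7,
                                            seed = 1L) {
  visits <- rep_len(visits, years)
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(points))) {
      pool <- sprintf("%s_sp%02d", substr(points$habitat[i], 1, 4),
                      seq_len(pool_size))
      R <- min(richness[i], pool_size)
      if (R == 0L) next
      spp <- sample(pool, R, prob = 0.8^(seq_len(pool_size) - 1L))
      for (y in seq_len(years)) for (v in seq_len(visits[y])) {
        det <- spp[runif(R) < p_detect]
        if (length(det))
          out[[length(out) + 1L]] <- data.frame(
            point_id = points$point_id[i], year = y, visit = v,
            species = det, distance = NA_real_, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Run the full synthetic study
#'
#' Chains every analysis step on one synthetic landscape: habitat mosaic,
#' fine and coarse reflectance, NDVI, moving-window texture, constrained
#' sample points, 100-m zonal summaries, foliage profiles and vegetation
#' structure indices, multi-year point-count surveys with distance-sampling
#' density estimation (six-model AIC sweep per year, across-year
#' averaging), simulated species richness with per-habitat accumulation
#' curves, habitat regressions with LOOCV and residual semivariograms, and
#' wall-to-wall predictive surfaces for density and richness. When
#' `out_dir` is given, tables are written as CSV, rasters as ESRI ASCII
#' grids, and a JSON manifest records the seed and models.
#'
#' @param seed master random seed.
#' @param out_dir optional output directory.
#' @param extent_m landscape extent (m).
#' @return list with all intermediate and final artifacts (see details).
#' @export
run_study <- function(seed = 1L, out_dir = NULL,
                      extent_m = c(2000, 2000)) {
  pd <- PIPELINE_DEFAULTS
  cfg <- truth_config(seed = seed)

  map <- generate_habitat_map(extent_m, pd$habitat_cell,
                              fractions = cfg$fractions, seed = seed)
  fine <- render_reflectance(map, "fine", cfg, seed = seed + 1L)
  coarse <- render_reflectance(map, "coarse", cfg, seed = seed + 2L)
  ndvi <- compute_ndvi(coarse$red, coarse$nir)

  pts <- place_sample_points(map, n_candidates = pd$n_candidates,
                             min_sep = pd$min_sep,
                             edge_buffer = pd$edge_buffer, seed = seed + 3L)

  var_fine <- focal_variance(fine, pd$richness_window)
  con_fine <- glcm_contrast(fine, pd$contrast_window)

  z_var <- zonal_summary(var_fine, pts, pd$zonal_radius, "variance_15")
  z_con <- zonal_summary(con_fine, pts, pd$zonal_radius, "contrast_51")
  z_ndvi <- zonal_summary(ndvi, pts, pd$zonal_radius, "ndvi")

  profiles <- simulate_foliage_profiles(pts, cfg, seed = seed + 4L)
  veg <- structure_indices(profiles)

  # grassland-obligate indicator species: density declines with the
  # local contrast (woody encroachment) covariate
  grass <- pts[pts$habitat == "grassland", , drop = FALSE]
  dens_cov <- z_con$sd[match(grass$point_id, z_con$point_id)] *
    pd$density_cov_scale
  obs <- simulate_bird_surveys(grass, dens_cov, cfg, seed = seed + 5L)
  dens <- density_pipeline(obs, grass)

  rich_cov <- z_var$sd * pd$richness_cov_scale
  rich <- simulate_richness(pts, rich_cov,
                            coefficients = cfg$richness_model$coefficients,
                            noise_sd = cfg$richness_model$noise_sd,
                            seed = seed + 6L)
  community <- simulate_community_observations(pts, rich$richness,
                                               seed = seed + 7L)
  curves <- lapply(split(community,
                         pts$habitat[match(community$point_id, pts$point_id)]),
                   function(o) accumulation_curve(incidence_matrix(o),
                                                  n_permutations = 200L,
                                                  seed = seed))

  rich_model <- fit_habitat_model(
    rich$richness, rich_cov,
    model_spec("richness", "variance_15_sd", quadratic = TRUE,
               measure = "variance", window = pd$richness_window))
  dens_y <- dens$average$density[match(grass$point_id, dens$average$point_id)]
  dens_model <- fit_habitat_model(
    dens_y, dens_cov,
    model_spec("density", "contrast_51_sd",
               measure = "contrast", window = pd$contrast_window))

  sv_rich <- residual_semivariogram(residuals(rich_model$fit),
                                    cbind(pts$x, pts$y))
  sv_dens <- residual_semivariogram(residuals(dens_model$fit),
                                    cbind(grass$x, grass$y))

  # wall-to-wall covariates: moving 100-m-scale SD of the texture rasters,
  # in the same scaled units as the zonal covariates
  sd_window <- 2L * round(pd$zonal_radius / pd$fine_cell) + 1L
  map_cov_rich <- focal_variance(var_fine, sd_window)
  map_cov_rich$values <- sqrt(map_cov_rich$values) * pd$richness_cov_scale
  map_cov_dens <- focal_variance(con_fine, sd_window)
  map_cov_dens$values <- sqrt(map_cov_dens$values) * pd$density_cov_scale
  surf_rich <- predict_surface(map_cov_rich, rich_model)
  surf_dens <- predict_surface(map_cov_dens, dens_model)

  res <- list(seed = seed, config = cfg, map = map, fine = fine,
              ndvi = ndvi, points = pts,
              zonal = rbind(z_var, z_con, z_ndvi),
              profiles = profiles, veg = veg,
              observations = obs, density = dens,
              richness = rich, community = community, curves = curves,
              richness_model = rich_model, density_model = dens_model,
              semivariograms = list(richness = sv_rich, density = sv_dens),
              surfaces = list(richness = surf_rich, density = surf_dens))
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_asc(res$map, p("habitat_map.asc"))
  write_asc(res$surfaces$richness, p("predicted_richness.asc"))
  write_asc(res$surfaces$density, p("predicted_density.asc"))
  write.csv(res$points, p("sample_points.csv"), row.names = FALSE)
  write.csv(res$zonal, p("zonal_summaries.csv"), row.names = FALSE)
  write.csv(res$profiles, p("foliage_profiles.csv"), row.names = FALSE)
  write.csv(res$veg, p("vegetation_indices.csv"), row.names = FALSE)
  write.csv(res$observations, p("bird_observations.csv"), row.names = FALSE)
  write.csv(res$density$per_year, p("density_per_year.csv"), row.names = FALSE)
  write.csv(res$density$average, p("density_average.csv"), row.names = FALSE)
  write.csv(res$richness, p("richness.csv"), row.names = FALSE)
  for (h in names(res$curves))
    write.csv(res$curves[[h]], p(sprintf("accumulation_%s.csv", h)),
              row.names = FALSE)
  manifest <- list(
    seed = res$seed,
    n_points = nrow(res$points),
    detection_models = lapply(res$density$models, function(m)
      list(key = m$key, adjustment = m$adjustment, n_terms = m$n_terms,
           parameters = as.numeric(m$par), logLik = m$logLik, AIC = m$AIC,
           p_hat = m$p_hat)),
    richness_model = list(coefficients = res$richness_model$coefficients,
                          adj_r_squared = res$richness_model$adj_r_squared,
                          p_value = res$richness_model$p_value,
                          loocv_error = res$richness_model$loocv_error),
    density_model = list(coefficients = res$density_model$coefficients,
                         adj_r_squared = res$density_model$adj_r_squared,
                         p_value = res$density_model$p_value,
                         loocv_error = res$density_model$loocv_error))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
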