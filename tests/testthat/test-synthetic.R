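test_that("habitat mosaic hits the requested class shares", {
  map <- generate_habitat_map(c(2000, 2000), 10, c(0.25, 0.35, 0.40),
                              patch_scale = 300, seed = 3)
  shares <- as.vector(table(factor(map$values, 1:3))) / length(map$values)
  expect_true(all(abs(shares - c(0.25, 0.35, 0.40)) < 0.03))
  # forced single class
  m1 <- generate_habitat_map(c(300, 300), 10, c(1, 0, 0), 50, seed = 3)
  expect_true(all(m1$values == 1))
  # determinism
  expect_identical(map$values,
                   generate_habitat_map(c(2000, 2000), 10,
                                        c(0.25, 0.35, 0.40), 300,
                                        seed = 3)$values)
  expect_error(generate_habitat_map(c(20, 20), 10, c(0.25, 0.35, 0.4), 50),
               "degenerate")
  expect_error(generate_habitat_map(c(300, 300), 10, c(0.5, 0.4, 0.2), 50),
               "sum")
})

test_that("savanna renders with the highest fine-grain local variance", {
  cfg <- truth_config()
  rasters <- lapply(1:3, function(cl)
    render_reflectance(uniform_map(cl, n = 20), "fine", cfg, seed = 5))
  mv <- vapply(rasters, function(r) mean(focal_variance(r, 3)$values), 0)
  expect_gt(mv[2], mv[1])   # savanna > grassland
  expect_gt(mv[2], mv[3])   # savanna > woodland
})

test_that("rendering is deterministic and degenerates to a constant", {
  cfg <- truth_config()
  cfg$reflectance$crown_cover[] <- 0
  cfg$reflectance$fine_noise_sd[] <- 0
  flat <- render_reflectance(uniform_map(1, n = 10), "fine", cfg, seed = 1)
  expect_equal(stats::sd(flat$values), 0)
  a <- render_reflectance(uniform_map(2, n = 10), "fine", seed = 9)
  b <- render_reflectance(uniform_map(2, n = 10), "fine", seed = 9)
  expect_identical(a$values, b$values)
  bad <- uniform_map(1, n = 10); bad$values[1, 1] <- 9
  expect_error(render_reflectance(bad, "fine"), "unknown habitat")
})

test_that("coarse rendering produces NDVI ordered by woody cover", {
  cfg <- truth_config()
  nd <- vapply(1:3, function(cl) {
    b <- render_reflectance(uniform_map(cl, n = 10, cell = 30), "coarse",
                            cfg, seed = 8, cell_size = 30)
    mean(compute_ndvi(b$red, b$nir)$values)
  }, 0)
  expect_true(nd[1] < nd[2] && nd[2] < nd[3])
})

test_that("sample-point constraints hold under exhaustive verification", {
  map <- generate_habitat_map(c(3000, 3000), 10, seed = 13)
  excl <- tex_raster(matrix(0, nrow(map$values), ncol(map$values)),
                     cell_size = 10)
  excl$values[150, ] <- 1  # a road across the landscape
  pts <- place_sample_points(map, n_candidates = 300, min_sep = 300,
                             exclusion_mask = excl, exclusion_radius = 150,
                             edge_buffer = 100, seed = 17)
  expect_gt(nrow(pts), 5)
  # pairwise separation, brute force over all retained pairs
  d <- as.matrix(stats::dist(pts[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(all(d >= 300))
  # exclusion clearance against every masked pixel center
  ex <- which(excl$values > 0, arr.ind = TRUE)
  exy <- cell_centers_y(excl)[ex[, 1]]; exx <- cell_centers_x(excl)[ex[, 2]]
  for (i in seq_len(nrow(pts)))
    expect_true(min(sqrt((exx - pts$x[i])^2 + (exy - pts$y[i])^2)) >= 150)
  # edge buffer against every other-class pixel center
  xs <- cell_centers_x(map); ys <- cell_centers_y(map)
  cls <- match(pts$habitat, c("grassland", "savanna", "woodland"))
  for (i in seq_len(nrow(pts))) {
    other <- which(map$values != cls[i], arr.ind = TRUE)
    d2 <- (xs[other[, 2]] - pts$x[i])^2 + (ys[other[, 1]] - pts$y[i])^2
    expect_true(min(d2) >= 100^2)
    # and the recorded habitat matches the map at the point
    rc <- point_to_cell(map, pts$x[i], pts$y[i])
    expect_equal(map$values[rc[1], rc[2]], cls[i])
  }
})

test_that("unsatisfiable constraints give an empty, warned result", {
  tiny <- uniform_map(1, n = 5, cell = 10)
  tiny$values[, 3] <- 2  # class edge everywhere within 100 m
  expect_warning(
    pts <- place_sample_points(tiny, n_candidates = 50, min_sep = 10,
                               edge_buffer = 100, seed = 2),
    "no sample point")
  expect_equal(nrow(pts), 0L)
})

test_that("foliage profiles recover the habitat FHD targets", {
  pts <- data.frame(point_id = sprintf("p%02d", 1:43),
                    x = 0, y = 0, habitat = "grassland",
                    stringsAsFactors = FALSE)
  targets <- c(grassland = 0.53, savanna = 1.51, woodland = 2.70)
  for (h in names(targets)) {
    pts$habitat <- h
    prof <- simulate_foliage_profiles(pts, seed = 7)
    expect_equal(nrow(prof), 16L * 43L)
    fhd <- structure_indices(prof)$fhd
    expect_lt(abs(mean(fhd) - targets[[h]]), 0.15)
  }
  # determinism
  p1 <- simulate_foliage_profiles(pts, seed = 3)
  p2 <- simulate_foliage_profiles(pts, seed = 3)
  expect_identical(p1, p2)
})

test_that("a single-band foliage distribution gives zero diversity", {
  cfg <- truth_config()
  cfg$foliage$band_weights$grassland <- 1  # all hits in band 1
  pts <- data.frame(point_id = "p1", x = 0, y = 0, habitat = "grassland")
  prof <- simulate_foliage_profiles(pts, cfg, seed = 1)
  expect_equal(structure_indices(prof)$fhd, 0)
})

test_that("bird surveys realize the analytic disc-average detectability", {
  pts <- data.frame(point_id = sprintf("p%03d", 1:200), x = 0, y = 0,
                    habitat = "grassland", stringsAsFactors = FALSE)
  cfg <- truth_config(detection_sigma = 40,
                      density_model = list(intercept = 5, slope = 0,
                                           quadratic = 0, covariate = "c"))
  obs <- simulate_bird_surveys(pts, rep(0, 200), cfg, years = 1L,
                               visits = 10L, seed = 21)
  expected_birds <- 5 * pi * 100^2 / 1e4 * 200 * 10
  frac <- nrow(obs) / expected_birds
  expect_lt(abs(frac - hn_pbar(40, 100)), 0.02)
  expect_true(all(obs$distance >= 0 & obs$distance <= 100))
  # near-infinite sigma detects essentially everything
  cfg$detection_sigma <- 1e6
  obs2 <- simulate_bird_surveys(pts, rep(0, 200), cfg, years = 1L,
                                visits = 2L, seed = 22)
  frac2 <- nrow(obs2) / (5 * pi * 100^2 / 1e4 * 200 * 2)
  expect_gt(frac2, 0.97)
  expect_lt(frac2, 1.03)
  cfg$detection_sigma <- -1
  expect_error(simulate_bird_surveys(pts, rep(0, 200), cfg, years = 1L),
               "sigma")
})

test_that("doubling density doubles detected counts within Monte Carlo error", {
  pts <- data.frame(point_id = sprintf("p%03d", 1:300), x = 0, y = 0,
                    habitat = "grassland", stringsAsFactors = FALSE)
  mk <- function(intercept, seed) {
    cfg <- truth_config(detection_sigma = 40,
                        density_model = list(intercept = intercept, slope = 0,
                                             quadratic = 0, covariate = "c"))
    nrow(simulate_bird_surveys(pts, rep(0, 300), cfg, years = 1L,
                               visits = 4L, seed = seed))
  }
  ratio <- mk(8, 31) / mk(4, 32)
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("richness simulation honors its closed forms and seed", {
  pts <- data.frame(point_id = c("a", "b", "c"), x = 0, y = 0,
                    habitat = "grassland")
  r <- simulate_richness(pts, c(0, 10, 20), c(7.08, 0.40, -0.0021),
                         noise_sd = 0, seed = 1)
  expect_equal(r$richness[1], 7L)  # round(7.08)
  expect_equal(r$richness[2], round(7.08 + 4 - 0.21))
  rc <- simulate_richness(pts, c(5, 50, 500), c(9.4, 0, 0), 0, seed = 1)
  expect_true(all(rc$richness == 9L))
  expect_identical(simulate_richness(pts, 1:3, seed = 5),
                   simulate_richness(pts, 1:3, seed = 5))
  expect_error(simulate_richness(pts, 1:3, noise_sd = -1), "noise_sd")
})
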