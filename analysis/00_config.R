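# Shared configuration for the analysis drivers. Every script regenerates
# what it needs deterministically from MASTER_SEED, so each is standalone.

library(texbird)

MASTER_SEED <- 42L
EXTENT_M <- c(2000, 2000)
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

make_landscape <- function() {
  cfg <- truth_config(seed = MASTER_SEED)
  map <- generate_habitat_map(EXTENT_M, 10, cfg$fractions,
                              seed = MASTER_SEED)
  fine <- render_reflectance(map, "fine", cfg, seed = MASTER_SEED + 1L)
  coarse <- render_reflectance(map, "coarse", cfg, seed = MASTER_SEED + 2L)
  pts <- place_sample_points(map, n_candidates = 800, min_sep = 100,
                             edge_buffer = 50, seed = MASTER_SEED + 3L)
  list(cfg = cfg, map = map, fine = fine, coarse = coarse, points = pts)
}
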