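#!/usr/bin/env Rscript
# Simulate the synthetic study landscape: a three-habitat mosaic
# (25% grassland / 35% savanna / 40% woodland), a 1-m single-band image,
# a 30-m red/NIR pair, and the constrained sample-point network.

source("analysis/00_config.R")

ls <- make_landscape()

shares <- table(factor(ls$map$values, 1:3)) / length(ls$map$values)
cat(sprintf("Habitat shares: grassland %.1f%%, savanna %.1f%%, woodland %.1f%%\n",
            100 * shares[1], 100 * shares[2], 100 * shares[3]))
cat(sprintf("Sample points: %d (%s)\n", nrow(ls$points),
            paste(sprintf("%s %d", names(table(ls$points$habitat)),
                          table(ls$points$habitat)), collapse = ", ")))
d <- as.matrix(dist(ls$points[, c("x", "y")])); diag(d) <- Inf
cat(sprintf("Minimum pairwise point separation: %.1f m\n", min(d)))

write_asc(ls$map, file.path(RESULTS_DIR, "habitat_map.asc"))
write_asc(ls$fine, file.path(RESULTS_DIR, "air_photo_1m.asc"))
write_asc(ls$coarse$red, file.path(RESULTS_DIR, "landsat_red_30m.asc"))
write_asc(ls$coarse$nir, file.path(RESULTS_DIR, "landsat_nir_30m.asc"))
write.csv(ls$points, file.path(RESULTS_DIR, "sample_points.csv"),
          row.names = FALSE)
cat("Wrote rasters and sample points to", RESULTS_DIR, "\n")
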