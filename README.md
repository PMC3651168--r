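# texbird

Remotely sensed **image texture** — the local spatial variation of pixel
values in a moving window — is a practical surrogate for vegetation
structure, the habitat attribute that field ecologists otherwise measure
plot by plot with telescoping poles. `texbird` implements, as a tested R
pipeline, an analysis that asks how well moving-window texture computed
from a fine-grain air photo (1 m) and from coarse-grain satellite NDVI
(30 m) predicts breeding-bird density and species richness across a
grassland / oak-savanna / oak-woodland mosaic, compared with two
field-measured indices (foliage-height diversity and horizontal vegetation
structure).

The pipeline is exercised end to end on a synthetic landscape generator
with known ground truth, so every estimator in the chain can be tested as
a recovery experiment.

## What it computes

* **Texture engine** — per-window statistics assigned to the central cell:

  - first-order variance: `sigma^2 = (1/n) * sum_i (x_i - x_bar)^2` over the
    window's `n = w^2` pixels (raw values);
  - first-order entropy: `H = -sum_k p_k ln p_k` over the window's
    gray-level frequencies (64 levels by default, nats);
  - second-order contrast from the gray-level co-occurrence matrix (GLCM):
    `C = sum_{i,j} p(i,j) * (i - j)^2`, symmetric accumulation, averaged
    over the four distance-1 offsets;
  - NDVI: `(NIR - Red) / (NIR + Red)`.

  Window extents follow the study design: 3–51 pixels at the 1-m grain,
  3–11 at the 30-m grain. All moving windows are computed with
  summed-area tables, so cost is independent of window size.

* **Zonal summaries** — mean and SD of any raster within 100 m of each
  sample point (pixel-center-in-circle rule).

* **Field vegetation structure** — foliage-height diversity (Shannon index
  over pooled 30-cm height-band hits from 16 profiles per point) and
  horizontal vegetation structure (SD of the 16 canopy heights).

* **Distance sampling** — point-transect likelihood for six key ×
  adjustment detection models (half-normal/uniform/hazard-rate ×
  cosine/polynomial/hermite series), AIC selection, average detectability
  `p_hat = (2/w^2) * int_0^w r g(r) dr`, per-point densities
  `D = count / (p_hat * pi w^2 * visits)`, and across-year averaging.

* **Richness and rarefaction** — per-point total richness and sample-based
  species-accumulation curves (exact enumeration of orderings when
  feasible, permutations otherwise).

* **Regression and mapping** — OLS with optional sqrt-response / log-
  predictor transforms and quadratic terms; adjusted R², overall-F
  p-values, leave-one-out cross-validation MSE, residual semivariograms
  (Matheron estimator), ranking tables that blank non-significant cells,
  and wall-to-wall predictive surfaces.

## Worked example

The numbered drivers under `analysis/` run the full study on the synthetic
landscape (2 km × 2 km, ~175 constrained sample points, 3 survey years):

```sh
Rscript analysis/01_simulate_landscape.R
Rscript analysis/02_texture_zonal.R
Rscript analysis/03_field_and_birds.R
Rscript analysis/04_models_and_maps.R
```

Output from a run (seed 42):

```
Habitat shares: grassland 25.0%, savanna 35.0%, woodland 40.0%
Sample points: 179 (grassland 52, savanna 57, woodland 70)

Mean foliage-height diversity by habitat (nats):
grassland   savanna  woodland
     0.51      1.48      2.65

  year 1: half-normal / none selected, p_hat = 0.543
  year 2: half-normal / none selected, p_hat = 0.510
  year 3: uniform / cosine selected, p_hat = 0.348
Mean across-year grassland density: 6.20 birds/ha

Adjusted R^2 of significant richness models (rows: measure x summary):
                 3    7   15   31   51
variance mean 0.11 0.13 0.09 0.06 0.06
variance sd   0.56 0.58 0.61 0.54 0.41
entropy mean  0.46 0.45   NA   NA   NA
entropy sd      NA 0.26   NA   NA   NA
contrast mean   NA   NA 0.08   NA 0.08
contrast sd     NA   NA 0.62   NA 0.50

Richness map model: y = 6.91 + 0.44 x + -0.0025 x^2 (adj R^2 0.61, LOOCV 22.7)
```

Reading this: the habitat mosaic and the field-structure gradient
(grassland < savanna < woodland foliage-height diversity) match the
configured truth; the AIC-selected detection functions recover per-year
detectabilities near the generating values; and the standard-deviation
zonal summaries of fine-grain texture carry most of the signal for
richness — the quadratic richness map model recovers the generating
coefficients (7.08, 0.40, −0.0021) within its confidence intervals. Blank
cells in the ranking table are models whose overall-F p-value exceeded
0.05. Predictive rasters and all tables land in `results/`.

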