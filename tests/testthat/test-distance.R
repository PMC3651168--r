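test_that("the flat uniform model needs no data and has p_hat 1", {
  set.seed(91)
  d <- runif(50, 0, 100)
  m <- fit_detection(d, "uniform", "none", 0, 100)
  expect_equal(m$p_hat, 1)
  expect_equal(m$k, 0L)
  expect_equal(m$AIC, -2 * m$logLik)
  # logLik of f(r) = 2 r / w^2 in closed form
  expect_equal(m$logLik, sum(log(2 * d / 100^2)), tolerance = 1e-12)
})

test_that("half-normal scale is recovered and p_hat matches the closed form", {
  set.seed(92)
  d <- sample_hn_radii(800, 40, 100)
  m <- fit_detection(d, "half-normal", "none", 0, 100)
  sigma_hat <- exp(m$par[1])
  expect_lt(abs(sigma_hat / 40 - 1), 0.1)
  # quadrature p_hat against the analytic half-normal disc average
  expect_equal(m$p_hat, hn_pbar(sigma_hat, 100), tolerance = 1e-6)
  expect_equal(average_detection_probability(m),
               hn_pbar(sigma_hat, 100), tolerance = 1e-6)
  # AIC is definitionally 2k - 2 logLik
  expect_equal(m$AIC, 2 * m$k - 2 * m$logLik, tolerance = 1e-12)
  expect_error(fit_detection(c(-5, 20), "half-normal"), "outside")
})

test_that("p_hat is monotone in sigma and tends to 1", {
  ph <- vapply(c(10, 20, 40, 80, 160, 1e4), function(s) {
    m <- structure(list(key = "half-normal", adjustment = "none",
                        n_terms = 0L, par = log(s), truncation = 100,
                        converged = TRUE), class = "detection_model")
    average_detection_probability(m)
  }, 0)
  expect_true(all(diff(ph) > 0))
  expect_equal(ph[length(ph)], 1, tolerance = 1e-4)
})

test_that("likelihood at the optimum dominates the truth", {
  set.seed(93)
  d <- sample_hn_radii(300, 40, 100)
  ll_at <- function(sigma) {
    g <- exp(-d^2 / (2 * sigma^2))
    mu <- 2 * sigma^2 * (1 - exp(-100^2 / (2 * sigma^2))) / 2  # int r g dr
    sum(log(d * g)) - length(d) * log(mu)
  }
  m <- fit_detection(d, "half-normal", "none", 0, 100)
  expect_gte(m$logLik, ll_at(40) - 1e-6)
  expect_equal(m$logLik, ll_at(exp(m$par[1])), tolerance = 1e-6)
})

test_that("AIC selection follows the argmin and its tie rules", {
  mk <- function(aic, k, key = "half-normal") {
    structure(list(key = key, adjustment = "none", n_terms = 0L,
                   AIC = aic, k = k, converged = TRUE),
              class = "detection_model")
  }
  sel <- select_detection_model(list(mk(100.2, 1), mk(99.1, 2), mk(105, 1)))
  expect_equal(sel$AIC, 99.1)
  # exact tie: fewer parameters win
  sel2 <- select_detection_model(list(mk(100, 3), mk(100, 2)))
  expect_equal(sel2$k, 2L)
  # still tied: fixed key order half-normal, uniform, hazard-rate
  sel3 <- select_detection_model(list(mk(100, 2, "hazard-rate"),
                                      mk(100, 2, "half-normal")))
  expect_equal(sel3$key, "half-normal")
  expect_error(select_detection_model(list()), "no converged")
})

test_that("the six-model sweep equals brute-force re-enumeration", {
  set.seed(94)
  d <- sample_hn_radii(400, 45, 100)
  sweep <- fit_detection_models(d, 100, max_terms = 1L)
  sel <- select_detection_model(sweep)
  # independent enumeration of every pair x term-count
  pairs <- list(c("half-normal", "cosine"), c("half-normal", "hermite-polynomial"),
                c("uniform", "cosine"), c("uniform", "simple-polynomial"),
                c("hazard-rate", "cosine"), c("hazard-rate", "simple-polynomial"))
  best_aic <- Inf
  for (p in pairs) for (m in 0:1) {
    if (p[1] == "uniform" && m == 0 && p[2] != "cosine") next
    f <- suppressWarnings(fit_detection(d, p[1],
                                        if (m == 0) "none" else p[2], m, 100))
    if (f$converged && f$AIC < best_aic) best_aic <- f$AIC
  }
  expect_equal(sel$AIC, best_aic, tolerance = 1e-9)
})

test_that("selected-model p_hat stays usable when the key is mimicked", {
  # uniform+cosine and hazard-rate can tie the half-normal in AIC; the
  # scientifically relevant output, average detectability, is centered on
  # the truth (individual fits can be ~30% off, the median is close)
  set.seed(95)
  truth <- hn_pbar(40, 100)
  ph <- replicate(12, {
    d <- sample_hn_radii(500, 40, 100)
    select_detection_model(fit_detection_models(d, 100))$p_hat
  })
  expect_true(all(ph / truth > 0.6 & ph / truth < 1.4))
  expect_lt(abs(median(ph) / truth - 1), 0.10)
})

test_that("densities scale as count / (p_hat * area * visits)", {
  pts <- data.frame(point_id = c("a", "b", "c"))
  obs <- data.frame(point_id = rep("a", 5), year = 1, visit = 1,
                    species = "X", distance = runif(5, 0, 90))
  flat <- fit_detection(runif(30, 0, 100), "uniform", "none", 0, 100)
  est <- point_densities(obs, pts, flat, visits = 1)
  expect_equal(est$density[est$point_id == "a"], 5 / (pi * 100^2 / 1e4),
               tolerance = 1e-12)  # 1.59 birds/ha
  expect_equal(est$density[est$point_id == "b"], 0)
  half <- flat; half$p_hat <- 0.5
  est2 <- point_densities(obs, pts, half, visits = 1)
  expect_equal(est2$density, est$density * 2)
})

test_that("across-year averaging is the unweighted mean with warnings", {
  est <- data.frame(point_id = c("a", "a", "a", "b"),
                    density = c(2, 4, 6, 5))
  avg <- multi_year_density(est)
  expect_equal(avg$density[avg$point_id == "a"], 4)
  expect_equal(avg$density[avg$point_id == "b"], 5)
  expect_warning(multi_year_density(est, all_points = c("a", "b", "c")),
                 "missing")
  same <- data.frame(point_id = "p", density = c(3, 3, 3))
  expect_equal(multi_year_density(same)$density, 3)
})

test_that("density recovery: estimates track the simulated truth", {
  pts <- data.frame(point_id = sprintf("p%03d", 1:60), x = 0, y = 0,
                    habitat = "grassland", stringsAsFactors = FALSE)
  cfg <- truth_config(detection_sigma = c(45, 45, 45),
                      density_model = list(intercept = 6, slope = 0,
                                           quadratic = 0, covariate = "c"))
  obs <- simulate_bird_surveys(pts, rep(0, 60), cfg, seed = 97)
  out <- density_pipeline(obs, pts)
  expect_lt(abs(mean(out$average$density) / 6 - 1), 0.15)
})
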