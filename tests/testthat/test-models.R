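test_that("noise-free fits are exact and match the normal equations", {
  x <- seq(1, 10, length.out = 20)
  m <- fit_habitat_model(2 + 3 * x, x)
  expect_equal(m$coefficients, c(2, 3), tolerance = 1e-10)
  expect_equal(m$adj_r_squared, 1, tolerance = 1e-10)
  # exact quadratic under a quadratic spec
  mq <- fit_habitat_model(1 - 2 * x + 0.5 * x^2, x,
                          model_spec(quadratic = TRUE))
  expect_lt(max(abs(residuals(mq$fit))), 1e-10)
  # random fixture vs closed-form least squares
  set.seed(121)
  y <- rnorm(30); xr <- rnorm(30)
  X <- cbind(1, xr)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  mr <- fit_habitat_model(y, xr)
  expect_equal(mr$coefficients, as.numeric(beta), tolerance = 1e-8)
  expect_error(fit_habitat_model(y, rep(1, 30)), "constant predictor")
})

test_that("transform flags act on the declared scales", {
  set.seed(122)
  x <- runif(25, 1, 9)
  y <- (1 + 0.5 * log(x) + rnorm(25, 0, 0.01))^2
  m <- fit_habitat_model(y, x, model_spec(sqrt_response = TRUE,
                                          log_predictor = TRUE))
  expect_equal(m$coefficients, c(1, 0.5), tolerance = 0.05)
  expect_equal(m$log_offset, 0)
  # zero predictor values flip the offset to log(x + 1)
  m2 <- fit_habitat_model(y, x - min(x), model_spec(log_predictor = TRUE))
  expect_equal(m2$log_offset, 1)
  expect_error(fit_habitat_model(-y, x, model_spec(sqrt_response = TRUE)),
               "y >= 0")
})

test_that("LOOCV equals the explicit refit loop for every spec", {
  set.seed(123)
  specs <- expand.grid(s = c(FALSE, TRUE), l = c(FALSE, TRUE),
                       q = c(FALSE, TRUE))
  for (i in seq_len(nrow(specs))) {
    sp <- model_spec(sqrt_response = specs$s[i], log_predictor = specs$l[i],
                     quadratic = specs$q[i])
    x <- runif(25, 0.5, 20)
    y <- abs(1 + 0.3 * x + rnorm(25))
    expect_equal(loocv_error(y, x, sp), oracle_loocv(y, x, sp),
                 tolerance = 1e-10)
  }
  # noise-free linear data cross-validates to ~0
  x <- 1:12
  expect_lt(loocv_error(5 + 2 * x, x, model_spec()), 1e-18)
})

test_that("semivariogram matches hand enumeration and the nugget level", {
  # constant residuals
  co <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  sv0 <- residual_semivariogram(rep(2, 10), co, n_bins = 5)
  expect_true(all(sv0$gamma[sv0$n_pairs > 0] == 0))
  # n = 6 fixture: all 15 pairs by hand
  set.seed(131)
  r6 <- rnorm(6); c6 <- cbind(runif(6, 0, 10), runif(6, 0, 10))
  sv <- residual_semivariogram(r6, c6, n_bins = 4, max_lag = 15)
  ij <- combn(6, 2)
  d <- sqrt(colSums((t(c6[ij[1, ], ]) - t(c6[ij[2, ], ]))^2))
  g2 <- (r6[ij[1, ]] - r6[ij[2, ]])^2
  for (b in 1:4) {
    lo <- (b - 1) * 15 / 4; hi <- b * 15 / 4
    sel <- d > lo & d <= hi | (b == 1 & d <= hi)
    expect_equal(sv$n_pairs[b], sum(sel))
    if (sum(sel)) expect_equal(sv$gamma[b], mean(g2[sel]) / 2,
                               tolerance = 1e-12)
  }
  expect_equal(sum(sv$n_pairs), 15L)
  # iid unit-variance residuals: every bin near gamma = 1
  set.seed(132)
  n <- 200
  svn <- residual_semivariogram(rnorm(n), cbind(runif(n, 0, 1000),
                                                runif(n, 0, 1000)))
  expect_true(all(abs(svn$gamma[svn$n_pairs > 30] - 1) < 0.25))
})

test_that("spatially independent residuals show no semivariogram trend", {
  set.seed(133)
  slopes <- replicate(20, {
    co <- cbind(runif(80, 0, 1000), runif(80, 0, 1000))
    sv <- residual_semivariogram(rnorm(80), co)
    ok <- sv$n_pairs > 0
    coef(lm(sv$gamma[ok] ~ sv$lag[ok]))[2]
  })
  expect_gt(t.test(slopes)$p.value, 0.05)
})

test_that("model ranking blanks non-significant cells and flags the best", {
  set.seed(134)
  mk <- function(measure, window, r2, p, loocv = 1) {
    structure(list(spec = model_spec(measure = measure, window = window),
                   adj_r_squared = r2, p_value = p, loocv_error = loocv),
              class = "habitat_model")
  }
  res <- list(mk("variance", 3, 0.45, 0.001), mk("variance", 7, 0.52, 0.02),
              mk("variance", 15, 0.30, 0.30), mk("entropy", 3, 0.20, 0.01),
              mk("entropy", 7, 0.10, 0.04), mk("entropy", 15, 0.05, 0.9))
  rk <- rank_candidate_models(res, alpha = 0.05)
  expect_true(is.na(rk$table["variance", "15"]))
  expect_true(is.na(rk$table["entropy", "15"]))
  expect_equal(rk$table["variance", "7"], 0.52)
  # best per measure equals the brute-force argmax over significant cells
  expect_equal(rk$best$window[rk$best$measure == "variance"], "7")
  expect_equal(rk$best$window[rk$best$measure == "entropy"], "3")
  only <- rank_candidate_models(res[4], alpha = 0.05)
  expect_equal(only$best$measure, "entropy")
})

test_that("prediction surfaces evaluate the published-style equations", {
  r <- tex_raster(matrix(c(10, 0, 30, NA), 2, 2))
  lin <- structure(list(spec = model_spec(), coefficients = c(9.22, -0.36),
                        log_offset = 0), class = "habitat_model")
  s <- predict_surface(r, lin)
  expect_equal(s$values[1, 1], 9.22 - 3.6)   # 5.62
  expect_equal(s$values[2, 1], 9.22)
  expect_equal(s$values[1, 2], 0)            # clamped negative
  expect_true(is.na(s$values[2, 2]))         # nodata propagates
  quad <- structure(list(spec = model_spec(quadratic = TRUE),
                         coefficients = c(7.08, 0.40, -0.0021),
                         log_offset = 0), class = "habitat_model")
  s2 <- predict_surface(tex_raster(matrix(0, 1, 1)), quad)
  expect_equal(s2$values[1, 1], 7.08)
  unclamped <- predict_surface(r, lin, clamp_nonnegative = FALSE)
  expect_lt(unclamped$values[1, 2], 0)
})
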