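#' @importFrom stats lm pf coef residuals fitted confint shapiro.test
#'   lm.influence median complete.cases
NULL

#' Regression model specification
#'
#' Declares the response/predictor pair and the transformations the fit
#' applies: optional square root of the response (count-derived densities),
#' optional log of the predictor, and an optional quadratic term. The log
#' transform uses `log(x)` when all predictor values are positive and
#' `log(x + 1)` otherwise (texture SD summaries can be exactly 0); the
#' offset actually used is recorded in the fitted result. Transformations
#' are never applied silently — only the flags set here.
#'
#' @param response,predictor labels for reporting.
#' @param sqrt_response take the square root of the response before fitting.
#' @param log_predictor log-transform the predictor before fitting.
#' @param quadratic add a quadratic term in the (transformed) predictor.
#' @param measure,window optional texture-measure and window labels used by
#'   [rank_candidate_models()].
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response = "y", predictor = "x",
                       sqrt_response = FALSE, log_predictor = FALSE,
                       quadratic = FALSE, measure = NA_character_,
                       window = NA) {
  structure(list(response = response, predictor = predictor,
                 sqrt_response = isTRUE(sqrt_response),
                 log_predictor = isTRUE(log_predictor),
                 quadratic = isTRUE(quadratic),
                 measure = measure, window = window),
            class = "model_spec")
}

transform_predictor <- function(x, spec) {
  offset <- 0
  if (spec$log_predictor) {
    if (any(x <= 0, na.rm = TRUE)) offset <- 1
    x <- log(x + offset)
  }
  list(x = x, log_offset = offset)
}

transform_response <- function(y, spec) {
  if (spec$sqrt_response) {
    if (any(y < 0, na.rm = TRUE)) stop("sqrt response requires y >= 0")
    sqrt(y)
  } else y
}

#' Fit one habitat regression model
#'
#' Ordinary least squares of the (transformed) response on the
#' (transformed) predictor, with an optional quadratic term. Reports the
#' coefficients, adjusted R^2 `1 - (1 - R^2)(n - 1)/(n - p - 1)`, the
#' overall-F model p-value, the leave-one-out cross-validation mean squared
#' prediction error on the transformed response scale, and simple
#' assumption diagnostics (residual spread ratio across the fitted-value
#' median split, Shapiro-Wilk normality p-value).
#'
#' @param y response vector (per point).
#' @param x predictor vector (per point).
#' @param spec a [model_spec()].
#' @return list of class `habitat_model`: `spec`, `coefficients`,
#'   `adj_r_squared`, `p_value`, `loocv_error`, `n`, `log_offset`,
#'   `diagnostics`, and the underlying `lm` fit.
#' @export
fit_habitat_model <- function(y, x, spec = model_spec()) {
  keep <- complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 5L) stop("need at least 5 complete observations")
  tp <- transform_predictor(x, spec)
  yt <- transform_response(y, spec)
  xt <- tp$x
  if (length(unique(xt)) < 2L) stop("singular design: constant predictor")
  dat <- data.frame(yt = yt, xt = xt)
  fit <- if (spec$quadratic) lm(yt ~ xt + I(xt^2), data = dat)
         else lm(yt ~ xt, data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  res <- residuals(fit)
  upper <- fitted(fit) > median(fitted(fit))
  spread_ratio <- if (sum(upper) > 1L && sum(!upper) > 1L)
    sd(res[upper]) / max(sd(res[!upper]), 1e-12) else NA_real_
  shapiro_p <- if (n >= 3L && n <= 5000L && sd(res) > 1e-12)
    shapiro.test(res)$p.value else NA_real_
  h <- lm.influence(fit, do.coef = FALSE)$hat
  structure(
    list(spec = spec,
         coefficients = unname(coef(fit)),
         adj_r_squared = sm$adj.r.squared,
         p_value = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                             lower.tail = FALSE)),
         loocv_error = mean((res / (1 - h))^2),
         n = n, log_offset = tp$log_offset,
         diagnostics = list(spread_ratio = spread_ratio,
                            shapiro_p = shapiro_p),
         fit = fit),
    class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  s <- x$spec
  form <- paste0(if (s$sqrt_response) "sqrt(y)" else "y", " ~ ",
                 if (s$log_predictor) "log(x)" else "x",
                 if (s$quadratic) " + x^2" else "")
  cat(sprintf("<habitat_model> %s vs %s [%s]\n", s$response, s$predictor, form))
  cat(sprintf("  n = %d, adj R^2 = %.3f, p = %.4g, LOOCV MSE = %.4g\n",
              x$n, x$adj_r_squared, x$p_value, x$loocv_error))
  cat("  coefficients:", paste(signif(x$coefficients, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Leave-one-out cross-validation prediction error
#'
#' Mean squared prediction error over the n leave-one-out refits, on the
#' transformed response scale. For ordinary least squares this equals the
#' hat-matrix identity `mean[(e_i / (1 - h_ii))^2]`, which is how it is
#' computed; the explicit n-refit loop is the independent check in the test
#' suite.
#'
#' @inheritParams fit_habitat_model
#' @return LOOCV mean squared prediction error (>= 0).
#' @export
loocv_error <- function(y, x, spec = model_spec()) {
  m <- fit_habitat_model(y, x, spec)
  if (any(lm.influence(m$fit, do.coef = FALSE)$hat >= 1 - 1e-12))
    stop("a leave-one-out refit is singular")
  m$loocv_error
}

#' Empirical semivariogram of model residuals
#'
#' Matheron estimator `gamma(h) = (1/2N(h)) sum (r_i - r_j)^2` over point
#' pairs whose separation falls in each lag bin; the standard check that
#' regression residuals carry no spatial autocorrelation.
#'
#' @param residuals numeric residual vector.
#' @param coords two-column matrix/data.frame of planar coordinates (m).
#' @param n_bins number of equal-width lag bins.
#' @param max_lag maximum lag (m); defaults to half the maximum pairwise
#'   distance.
#' @return data.frame `lag` (bin center), `gamma`, `n_pairs`; empty bins
#'   have `n_pairs = 0` and `NA` gamma.
#' @export
residual_semivariogram <- function(residuals, coords, n_bins = 10L,
                                   max_lag = NULL) {
  coords <- as.matrix(coords)
  stopifnot(length(residuals) == nrow(coords), ncol(coords) == 2L)
  d <- as.vector(stats::dist(coords))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (max_lag <= 0) stop("max_lag must be > 0")
  ij <- utils::combn(length(residuals), 2L)
  dr2 <- (residuals[ij[1L, ]] - residuals[ij[2L, ]])^2
  keep <- d <= max_lag
  bin <- pmin(ceiling(d[keep] / (max_lag / n_bins)), n_bins)
  bin[bin == 0L] <- 1L
  np <- tabulate(bin, nbins = n_bins)
  gs <- vapply(seq_len(n_bins), function(b) sum(dr2[keep][bin == b]), 0)
  data.frame(lag = (seq_len(n_bins) - 0.5) * max_lag / n_bins,
             gamma = ifelse(np > 0, gs / (2 * np), NA_real_),
             n_pairs = np)
}

#' Rank candidate models across texture measures and window extents
#'
#' Mirrors the published ranking-table layout: one row per measure x
#' summary, one column per window extent, cells holding adjusted R^2 only
#' when the model p-value is at or below `alpha` (blank otherwise); the
#' best significant model per row (highest adjusted R^2) is flagged and its
#' LOOCV prediction error reported.
#'
#' @param results list of [fit_habitat_model()] results whose specs carry
#'   `measure` and `window` labels and share a response.
#' @param alpha significance threshold (default 0.05).
#' @return list: `table` (wide data.frame of adjusted R^2, NA = not
#'   significant), `best` (data.frame `measure`, `window`,
#'   `adj_r_squared`, `p_value`, `loocv_error`).
#' @export
rank_candidate_models <- function(results, alpha = 0.05) {
  meas <- vapply(results, function(r) as.character(r$spec$measure), "")
  win <- vapply(results, function(r) as.character(r$spec$window), "")
  r2 <- vapply(results, `[[`, 0, "adj_r_squared")
  pv <- vapply(results, `[[`, 0, "p_value")
  le <- vapply(results, `[[`, 0, "loocv_error")
  sig <- pv <= alpha
  mlev <- unique(meas); wlev <- unique(win)
  tab <- matrix(NA_real_, length(mlev), length(wlev),
                dimnames = list(mlev, wlev))
  for (i in seq_along(results)) if (sig[i]) tab[meas[i], win[i]] <- r2[i]
  best <- do.call(rbind, lapply(mlev, function(m) {
    idx <- which(meas == m & sig)
    if (!length(idx)) return(NULL)
    b <- idx[which.max(r2[idx])]
    data.frame(measure = m, window = win[b], adj_r_squared = r2[b],
               p_value = pv[b], loocv_error = le[b],
               stringsAsFactors = FALSE)
  }))
  list(table = as.data.frame(tab), best = best)
}

#' Evaluate a fitted model over a covariate raster
#'
#' Pixelwise prediction: the covariate is transformed per the model's spec
#' (log with the recorded offset), the fitted polynomial evaluated, and
#' square-root responses back-transformed by squaring. Negative predictions
#' are optionally clamped to 0 (densities cannot be negative). Nodata
#' propagates.
#'
#' @param covariate a [tex_raster] in the model's predictor units.
#' @param result a [fit_habitat_model()] result.
#' @param clamp_nonnegative clamp negative predictions to 0.
#' @return a [tex_raster] of predictions.
#' @export
predict_surface <- function(covariate, result, clamp_nonnegative = TRUE) {
  stopifnot(is_tex_raster(covariate))
  x <- covariate$values
  if (result$spec$log_predictor) x <- log(x + result$log_offset)
  co <- result$coefficients
  pred <- co[1L] + co[2L] * x
  if (length(co) >= 3L) pred <- pred + co[3L] * x^2
  if (result$spec$sqrt_response) pred <- pmax(pred, 0)^2
  if (clamp_nonnegative) pred <- pmax(pred, 0)
  pred[is.na(covariate$values)] <- NA_real_
  tex_raster(pred, covariate$origin_x, covariate$origin_y,
             covariate$cell_size)
}
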