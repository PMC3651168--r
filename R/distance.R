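#' @importFrom stats optim optimize integrate sd aggregate
NULL

DETECTION_KEYS <- c("half-normal", "uniform", "hazard-rate")

# Key functions, all with g(0) = 1. Parameters arrive on an unconstrained
# scale: log(sigma) for half-normal; log(sigma), log(b - 1) for hazard-rate
# (shape b > 1 keeps the shoulder and a finite point-transect likelihood).
key_fun <- function(key, r, kp) {
  switch(key,
    "half-normal" = exp(-r^2 / (2 * exp(2 * kp[1]))),
    "uniform" = rep(1, length(r)),
    "hazard-rate" = {
      sigma <- exp(kp[1]); b <- 1 + exp(kp[2])
      z <- (r / sigma)^(-b)
      out <- -expm1(-z)
      out[r == 0] <- 1
      out
    })
}

n_key_par <- function(key) switch(key, "half-normal" = 1L, "uniform" = 0L,
                                  "hazard-rate" = 2L)

# Probabilists' Hermite polynomials of even order used by the hermite series.
hermite_even <- function(x, order) {
  switch(as.character(order),
    "4" = x^4 - 6 * x^2 + 3,
    "6" = x^6 - 15 * x^4 + 45 * x^2 - 15,
    "8" = x^8 - 28 * x^6 + 210 * x^4 - 420 * x^2 + 105,
    stop("unsupported hermite order"))
}

# Adjustment series factor 1 + sum_j a_j h_j(.). Cosine terms start at order
# 1 for the uniform key and order 2 for the shaped keys (the conventional
# series); simple polynomials are (r/w)^4, (r/w)^6, ...; hermite terms are
# He_4, He_6, ... of the key-scaled distance.
series_fun <- function(adjustment, key, r, w, kp, a) {
  if (!length(a)) return(rep(1, length(r)))
  z <- r / w
  s <- rep(1, length(r))
  for (j in seq_along(a)) {
    h <- switch(adjustment,
      "cosine" = {
        ord <- if (key == "uniform") j else j + 1L
        cos(ord * pi * z)
      },
      "simple-polynomial" = z^(2 * (j + 1L)),
      "hermite-polynomial" = {
        zs <- r / exp(kp[1])
        hermite_even(zs, 2L * (j + 1L)) / hermite_even(0, 2L * (j + 1L))
      },
      "none" = stop("'none' adjustment carries no terms"))
    s <- s + a[j] * h
  }
  s
}

# Unnormalized detection function key(r) * series(r); the point-transect
# likelihood is invariant to its scale, and g(0) = 1 after normalization.
g_unnorm <- function(key, adjustment, r, w, par) {
  nk <- n_key_par(key)
  kp <- par[seq_len(nk)]
  a <- par[-seq_len(nk)]
  if (nk == 0L) a <- par
  key_fun(key, r, kp) * series_fun(adjustment, key, r, w, kp, a)
}

detect_g <- function(model, r) {
  gu <- g_unnorm(model$key, model$adjustment, r, model$truncation, model$par)
  g0 <- g_unnorm(model$key, model$adjustment, 0, model$truncation, model$par)
  gu / g0
}

#' Fit one key x adjustment detection function to radial distances
#'
#' Maximizes the conventional point-transect distance-sampling likelihood:
#' detected radii have density proportional to `r g(r)` on `[0, w]`. The
#' average detection probability is `p_hat = (2 / w^2) integral r g(r) dr`.
#' Fits whose detection function is not monotone non-increasing on a grid
#' (beyond a small ripple tolerance) are flagged as non-converged, a
#' standard guard against implausible adjustment-series shapes.
#'
#' @param distances radial distances (m) of detected birds, in `[0, w]`.
#' @param key `"half-normal"`, `"uniform"` or `"hazard-rate"`.
#' @param adjustment `"cosine"`, `"simple-polynomial"`,
#'   `"hermite-polynomial"` or `"none"`.
#' @param n_terms number of adjustment terms (0-3).
#' @param truncation truncation radius w (m).
#' @return an object of class `detection_model`: key, adjustment,
#'   parameters, `logLik`, `k`, `AIC`, `p_hat`, `converged`, `n`.
#' @export
fit_detection <- function(distances, key = "half-normal",
                          adjustment = "none", n_terms = 0L,
                          truncation = 100) {
  key <- match.arg(key, DETECTION_KEYS)
  adjustment <- match.arg(adjustment, c("cosine", "simple-polynomial",
                                        "hermite-polynomial", "none"))
  if (adjustment == "none") n_terms <- 0L
  if (n_terms < 0L || n_terms > 3L) stop("n_terms must be 0..3")
  if (adjustment != "none" && n_terms == 0L) adjustment <- "none"
  if (any(distances < 0 | distances > truncation))
    stop("distances outside [0, truncation]")
  n <- length(distances)
  if (n < 10L) warning("fewer than 10 observations: unstable detection fit")
  w <- truncation
  gl <- pracma::gaussLegendre(61, 0, w)
  # f(r) = r g(r) / mu: the sum of log r_i is a data constant of the
  # likelihood (distances at exactly 0 are perturbed to half a millimetre)
  log_r_sum <- sum(log(pmax(distances, 5e-4)))

  nk <- n_key_par(key)
  npar <- nk + n_terms
  negll <- function(par) {
    gu <- g_unnorm(key, adjustment, distances, w, par)
    gq <- g_unnorm(key, adjustment, gl$x, w, par)
    if (any(!is.finite(gu)) || any(!is.finite(gq)) ||
        any(gu <= 0) || any(gq < 0)) return(1e10)
    mu <- sum(gl$w * gl$x * gq)
    if (!is.finite(mu) || mu <= 0) return(1e10)
    -(log_r_sum + sum(log(gu)) - n * log(mu))
  }

  converged <- TRUE
  if (npar == 0L) {
    par <- numeric(0)
    ll <- -negll(par)
  } else {
    start <- c(switch(key,
                      "half-normal" = log(sqrt(mean(distances^2) / 2)),
                      "hazard-rate" = c(log(max(stats::median(distances), 1)),
                                        log(1.5)),
                      "uniform" = numeric(0)),
               rep(0, n_terms))
    fit <- if (npar == 1L) {
      optimize(negll, interval = start[1] + c(-4, 4))
    } else {
      optim(start, negll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10))
    }
    if (npar == 1L) {
      par <- fit$minimum; ll <- -fit$objective
    } else {
      par <- fit$par; ll <- -fit$value
      converged <- fit$convergence == 0L
    }
    if (!is.finite(ll) || ll <= -1e9) converged <- FALSE
  }

  model <- structure(
    list(key = key, adjustment = adjustment, n_terms = n_terms,
         par = par, logLik = ll, k = npar, AIC = 2 * npar - 2 * ll,
         truncation = w, n = n, converged = converged),
    class = "detection_model")
  # monotonicity spot-check on a grid (ripple tolerance 1% of g(0))
  if (converged && npar > 0L) {
    g <- detect_g(model, seq(0, w, length.out = 101L))
    if (any(diff(g) > 0.01) || any(g < -1e-8)) model$converged <- FALSE
  }
  model$p_hat <- if (model$converged) average_detection_probability(model)
                 else NA_real_
  model
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model> %s / %s (%d term%s)\n", x$key, x$adjustment,
              x$n_terms, if (x$n_terms == 1L) "" else "s"))
  cat(sprintf("  n = %d, w = %g m, logLik = %.3f, AIC = %.3f, p_hat = %.4f%s\n",
              x$n, x$truncation, x$logLik, x$AIC, x$p_hat,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Average detection probability within the truncation radius
#'
#' `p_hat = (2 / w^2) integral_0^w r g(r) dr` by adaptive quadrature; the
#' expected fraction of birds in the count disc that are detected.
#'
#' @param model a converged [fit_detection()] model.
#' @return p_hat in (0, 1].
#' @export
average_detection_probability <- function(model) {
  w <- model$truncation
  if (model$key == "uniform" && model$n_terms == 0L) return(1)
  val <- integrate(function(r) r * detect_g(model, r), 0, w,
                   rel.tol = 1e-9, abs.tol = 1e-12)$value
  min(max(2 * val / w^2, .Machine$double.eps), 1)
}

#' Fit the six-model detection sweep
#'
#' The default candidate set pairs each key with its conventional series:
#' half-normal cosine, half-normal hermite-polynomial, uniform cosine,
#' uniform simple-polynomial, hazard-rate cosine and hazard-rate
#' simple-polynomial. For each pair, adjustment orders `0 .. max_terms` are
#' fitted and the best AIC among converged fits represents the pair.
#'
#' @inheritParams fit_detection
#' @param max_terms maximum number of adjustment terms per pair.
#' @return list of `detection_model` objects (one per pair that converged).
#' @export
fit_detection_models <- function(distances, truncation = 100, max_terms = 1L) {
  pairs <- list(c("half-normal", "cosine"),
                c("half-normal", "hermite-polynomial"),
                c("uniform", "cosine"),
                c("uniform", "simple-polynomial"),
                c("hazard-rate", "cosine"),
                c("hazard-rate", "simple-polynomial"))
  out <- list()
  for (p in pairs) {
    best <- NULL
    for (m in 0:max_terms) {
      if (p[1] == "uniform" && m == 0L && p[2] != "cosine") next
      fit <- suppressWarnings(
        fit_detection(distances, key = p[1],
                      adjustment = if (m == 0L) "none" else p[2],
                      n_terms = m, truncation = truncation))
      if (fit$converged && (is.null(best) || fit$AIC < best$AIC)) best <- fit
    }
    if (!is.null(best)) {
      best$pair <- paste(p, collapse = " ")
      out[[length(out) + 1L]] <- best
    }
  }
  out
}

#' Select the detection model by AIC
#'
#' Minimum AIC wins; exact ties go to the model with fewer parameters, then
#' to the fixed key order half-normal, uniform, hazard-rate.
#'
#' @param models list of `detection_model` objects.
#' @return the selected `detection_model`.
#' @export
select_detection_model <- function(models) {
  models <- Filter(function(m) isTRUE(m$converged), models)
  if (!length(models)) stop("no converged detection model to select from")
  aic <- vapply(models, `[[`, 0, "AIC")
  k <- vapply(models, `[[`, 0, "k")
  keyord <- match(vapply(models, `[[`, "", "key"), DETECTION_KEYS)
  models[[order(aic, k, keyord)[1L]]]
}

#' Per-point densities for one species and year
#'
#' `density = detected count / (p_hat x disc area x visits)`, in birds per
#' hectare; points with no detections get density 0. Counts are summed over
#' the year's visits, so the estimate is a per-survey density.
#'
#' @param observations data.frame `point_id`, `year`, `visit`, `species`,
#'   `distance`, filtered to one species and year.
#' @param points data.frame with `point_id` (defines the full point set).
#' @param model the selected `detection_model`.
#' @param visits number of visits contributing to the counts.
#' @return data.frame `point_id`, `year`, `density`, `count`, `p_hat`.
#' @export
point_densities <- function(observations, points, model, visits) {
  if (!isTRUE(model$converged)) stop("model did not converge")
  counts <- table(factor(observations$point_id, levels = points$point_id))
  area_ha <- pi * model$truncation^2 / 1e4
  yr <- if (nrow(observations)) observations$year[1L] else NA_integer_
  data.frame(point_id = points$point_id,
             year = yr,
             density = as.numeric(counts) / (model$p_hat * area_ha * visits),
             count = as.integer(counts),
             p_hat = model$p_hat,
             stringsAsFactors = FALSE)
}

#' Across-year average of per-point densities
#'
#' Unweighted arithmetic mean over the years in which a point has an
#' estimate; points missing from every year are dropped with a warning.
#'
#' @param estimates data.frame rbind of [point_densities()] outputs.
#' @param all_points optional character vector of the full point set, used
#'   to warn about points with no estimate in any year.
#' @return data.frame `point_id`, `density` (across-year mean).
#' @export
multi_year_density <- function(estimates, all_points = NULL) {
  out <- aggregate(density ~ point_id, data = estimates, FUN = mean)
  if (!is.null(all_points)) {
    missing <- setdiff(all_points, out$point_id)
    if (length(missing))
      warning(sprintf("%d point(s) missing from all years were excluded",
                      length(missing)))
  }
  out[order(out$point_id), , drop = FALSE]
}

#' Full density workflow: sweep, select, estimate, average
#'
#' For each survey year, fits the six-model sweep to that year's distances,
#' selects by AIC, converts counts to per-point densities, then averages
#' across years.
#'
#' @param observations data.frame `point_id`, `year`, `visit`, `species`,
#'   `distance` for one species.
#' @param points data.frame with `point_id`.
#' @param visits visits per year (recycled over observed years).
#' @param truncation truncation radius (m).
#' @param max_terms maximum adjustment terms in the sweep.
#' @return list: `per_year` (data.frame), `average` (data.frame),
#'   `models` (selected model per year).
#' @export
density_pipeline <- function(observations, points, visits = c(4L, 4L, 3L),
                             truncation = 100, max_terms = 1L) {
  yrs <- sort(unique(observations$year))
  visits <- rep_len(visits, length(yrs))
  per_year <- list(); models <- list()
  for (i in seq_along(yrs)) {
    obs <- observations[observations$year == yrs[i], , drop = FALSE]
    sweep <- fit_detection_models(obs$distance, truncation = truncation,
                                  max_terms = max_terms)
    sel <- select_detection_model(sweep)
    models[[as.character(yrs[i])]] <- sel
    per_year[[i]] <- point_densities(obs, points, sel, visits[i])
  }
  per_year <- do.call(rbind, per_year)
  list(per_year = per_year,
       average = multi_year_density(per_year, points$point_id),
       models = models)
}
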