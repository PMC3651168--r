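# Independent naive oracles and fixture builders. Everything here recomputes
# the statistics by literal definition (per-window double loops, exhaustive
# pair enumeration), deliberately sharing no code with the package internals.

random_raster <- function(nr, nc, na_frac = 0, seed = NULL,
                          vals = function(n) runif(n, 0, 255)) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(vals(nr * nc), nr, nc)
  if (na_frac > 0) v[sample(length(v), round(na_frac * length(v)))] <- NA
  tex_raster(v)
}

# mirror reflection padding (edge not repeated), written independently
oracle_pad <- function(m, k) {
  if (k == 0) return(m)
  ri <- c(rev(seq_len(k)) + 1, seq_len(nrow(m)), nrow(m) - seq_len(k))
  ci <- c(rev(seq_len(k)) + 1, seq_len(ncol(m)), ncol(m) - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# generic per-window naive focal: applies `f` to each w x w window of the
# reflect-padded matrix; edge_policy "mask" leaves an NA border instead
oracle_focal <- function(m, w, f, edge_policy = "reflect") {
  h <- (w - 1) / 2
  M <- if (edge_policy == "reflect") oracle_pad(m, h) else m
  out <- matrix(NA_real_, nrow(m), ncol(m))
  rows <- if (edge_policy == "reflect") seq_len(nrow(m)) else
    (h + 1):(nrow(m) - h)
  cols <- if (edge_policy == "reflect") seq_len(ncol(m)) else
    (h + 1):(ncol(m) - h)
  off <- if (edge_policy == "reflect") h else 0
  for (i in rows) for (j in cols) {
    win <- M[(i - h + off):(i + h + off), (j - h + off):(j + h + off)]
    out[i, j] <- f(win)
  }
  out[is.na(m)] <- NA_real_
  out
}

oracle_variance <- function(m, w, edge_policy = "reflect") {
  oracle_focal(m, w, function(win) {
    v <- win[!is.na(win)]
    if (!length(v)) return(NA_real_)
    mean((v - mean(v))^2)
  }, edge_policy)
}

oracle_entropy <- function(q, w, edge_policy = "reflect") {
  oracle_focal(q, w, function(win) {
    v <- win[!is.na(win)]
    if (!length(v)) return(NA_real_)
    p <- table(v) / length(v)
    -sum(p * log(p))
  }, edge_policy)
}

oracle_contrast <- function(q, w, offsets, edge_policy = "reflect") {
  oracle_focal(q, w, function(win) {
    per_off <- vapply(offsets, function(off) {
      s <- 0; n <- 0L
      for (i in seq_len(w)) for (j in seq_len(w)) {
        i2 <- i + off[1]; j2 <- j + off[2]
        if (i2 >= 1 && i2 <= w && j2 >= 1 && j2 <= w &&
            !is.na(win[i, j]) && !is.na(win[i2, j2])) {
          s <- s + (win[i, j] - win[i2, j2])^2
          n <- n + 1L
        }
      }
      if (n == 0L) NA_real_ else s / n
    }, 0)
    if (all(is.na(per_off))) NA_real_ else mean(per_off, na.rm = TRUE)
  }, edge_policy)
}

# radii from a truncated half-normal point-transect pdf f(r) propto r g(r),
# by rejection from uniform-in-disc placement
sample_hn_radii <- function(n, sigma, w) {
  out <- numeric(0)
  while (length(out) < n) {
    r <- w * sqrt(runif(2L * n))
    keep <- runif(2L * n) < exp(-r^2 / (2 * sigma^2))
    out <- c(out, r[keep])
  }
  out[seq_len(n)]
}

# analytic disc-average detectability of a half-normal within radius w
hn_pbar <- function(sigma, w) 2 * sigma^2 * (1 - exp(-w^2 / (2 * sigma^2))) / w^2

# single-habitat map fixture
uniform_map <- function(class_id, n = 30, cell = 10) {
  m <- tex_raster(matrix(class_id, n, n), cell_size = cell)
  attr(m, "habitats") <- c("grassland", "savanna", "woodland")
  m
}

# explicit leave-one-out refit loop (the brute-force LOOCV oracle): the
# transformation, including the log offset, is fixed on the full data — it
# is part of the model specification — and each refit is a literal lm()
oracle_loocv <- function(y, x, spec) {
  xt <- if (spec$log_predictor) {
    log(x + if (any(x <= 0)) 1 else 0)
  } else x
  yt <- if (spec$sqrt_response) sqrt(y) else y
  form <- if (spec$quadratic) yt ~ xt + I(xt^2) else yt ~ xt
  n <- length(y)
  errs <- vapply(seq_len(n), function(i) {
    d <- data.frame(yt = yt[-i], xt = xt[-i])
    fit <- lm(form, data = d)
    pred <- predict(fit, newdata = data.frame(xt = xt[i]))
    (yt[i] - pred)^2
  }, 0)
  mean(errs)
}
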