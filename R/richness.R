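#' Total species richness at a sample point
#'
#' Number of distinct species codes ever recorded at the point, pooled
#' across all years and visits (zero when the point has no observations).
#'
#' @param observations data.frame with `point_id` and `species`.
#' @param point_id the point to summarize.
#' @return non-negative integer.
#' @export
total_richness <- function(observations, point_id) {
  length(unique(observations$species[observations$point_id == point_id]))
}

#' Sample-by-species incidence matrix
#'
#' One row per survey event (by default a point x year x visit combination),
#' one column per species, entries 0/1.
#'
#' @param observations data.frame of bird records.
#' @param sample_cols columns whose combination defines one sample.
#' @return binary integer matrix with sample ids as row names.
#' @export
incidence_matrix <- function(observations,
                             sample_cols = c("point_id", "year", "visit")) {
  sample_id <- do.call(paste, c(observations[sample_cols], sep = "|"))
  tab <- table(sample_id, observations$species)
  m <- (unclass(tab) > 0) + 0L
  matrix(m, nrow(tab), ncol(tab),
         dimnames = list(rownames(tab), colnames(tab)))
}

# All permutations of 1..n (n small).
all_orderings <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_orderings(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (k in seq_len(n)) for (s in sub) {
    i <- i + 1L
    out[[i]] <- c(k, ifelse(s >= k, s + 1L, s))
  }
  out
}

#' Species-accumulation (rarefaction) curve
#'
#' Mean and standard deviation of the cumulative number of distinct species
#' as samples accumulate, over random orderings of the samples. When the
#' number of possible orderings does not exceed `n_permutations` the mean
#' and sd are computed exactly over all orderings; otherwise
#' `n_permutations` random orderings are drawn (deterministic given
#' `seed`).
#'
#' @param incidence binary sample-by-species matrix ([incidence_matrix()]).
#' @param n_permutations number of sample orderings (>= 1).
#' @param seed random seed.
#' @return data.frame of class `accumulation_curve`: `k`, `mean_richness`,
#'   `sd`, with attributes `n_permutations` and `exact`.
#' @export
accumulation_curve <- function(incidence, n_permutations = 1000L, seed = 1L) {
  incidence <- (as.matrix(incidence) > 0) + 0L
  S <- nrow(incidence)
  if (S < 1L) stop("need at least one sample")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  exact <- factorial(S) <= n_permutations
  orders <- if (exact) all_orderings(S) else
    with_seed(seed, replicate(n_permutations, sample.int(S), simplify = FALSE))
  rich <- vapply(orders, function(ord) {
    seen <- logical(ncol(incidence))
    out <- integer(S)
    for (k in seq_len(S)) {
      seen <- seen | incidence[ord[k], ] > 0
      out[k] <- sum(seen)
    }
    out
  }, integer(S))
  rich <- matrix(rich, nrow = S)
  means <- rowMeans(rich)
  sds <- apply(rich, 1L, function(v) sqrt(mean((v - mean(v))^2)))
  out <- data.frame(k = seq_len(S), mean_richness = means, sd = sds)
  attr(out, "n_permutations") <- length(orders)
  attr(out, "exact") <- exact
  class(out) <- c("accumulation_curve", "data.frame")
  out
}
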