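#' Sample-based rarefaction curve
#'
#' Expected species count among random subsets of m plots, m = 1..N, used
#' to assess sampling sufficiency at each scale.  Each resample draws a
#' random permutation of the plots and accumulates richness along it, so
#' every individual accumulation curve -- and hence the mean -- is monotone
#' non-decreasing, and the m = N endpoint equals the total observed
#' richness with zero CI width.
#'
#' @param occ an `occurrence_matrix`.
#' @param n_resamples number of random plot orderings (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `n_plots`, `mean_richness`, `ci_low`,
#'   `ci_high` (2.5/97.5 percentiles over resamples).
#' @seealso [rarefaction_exact()] for the closed-form expectation.
#' @export
rarefaction_curve <- function(occ, n_resamples = 200L, seed = 1L) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  n <- nrow(occ)
  m <- unclass(occ)
  set.seed(as.integer(seed))
  acc <- matrix(0L, n, n_resamples)
  for (b in seq_len(n_resamples)) {
    perm <- sample.int(n)
    seen <- apply(m[perm, , drop = FALSE] > 0L, 2L, cummax)
    if (n == 1L) seen <- matrix(seen, nrow = 1L)
    acc[, b] <- as.integer(rowSums(seen))
  }
  data.frame(
    n_plots = seq_len(n),
    mean_richness = rowMeans(acc),
    ci_low = apply(acc, 1L, quantile, probs = 0.025, names = FALSE),
    ci_high = apply(acc, 1L, quantile, probs = 0.975, names = FALSE)
  )
}

#' Exact sample-based rarefaction expectation
#'
#' Closed-form (hypergeometric) expected richness in a random subset of m
#' plots: `E[S_m] = sum_s (1 - choose(N - n_s, m) / choose(N, m))` where
#' `n_s` is the number of plots occupied by species s.  Serves as the
#' deterministic backend / oracle for [rarefaction_curve()].
#'
#' @param occ an `occurrence_matrix`.
#' @return data.frame with columns `n_plots`, `mean_richness`.
#' @export
rarefaction_exact <- function(occ) {
  n <- nrow(occ)
  ns <- colSums(unclass(occ) > 0L)
  mean_rich <- vapply(seq_len(n), function(m) {
    # log-scale ratio; choose(N - n_s, m) = 0 when m > N - n_s
    p_absent <- ifelse(m > n - ns, 0,
                       exp(lchoose(n - ns, m) - lchoose(n, m)))
    sum(1 - p_absent)
  }, numeric(1))
  data.frame(n_plots = seq_len(n), mean_richness = mean_rich)
}
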