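#' Great-circle distance matrix
#'
#' Haversine distances in metres between WGS84 points.
#'
#' @param lon,lat numeric vectors of coordinates in decimal degrees.
#' @return symmetric n x n matrix of distances (m).
#' @export
haversine_matrix <- function(lon, lat) {
  R <- 6371008.8
  phi <- lat * pi / 180; lam <- lon * pi / 180
  dphi <- outer(phi, phi, "-"); dlam <- outer(lam, lam, "-")
  a <- sin(dphi / 2)^2 + outer(cos(phi), cos(phi)) * sin(dlam / 2)^2
  a[a > 1] <- 1
  2 * R * asin(sqrt(a))
}

# row-standardized kNN weight matrix on great-circle distance
.knn_weights <- function(lon, lat, k) {
  n <- length(lon)
  if (n <= k) stop("need more points than neighbours")
  d <- haversine_matrix(lon, lat)
  diag(d) <- Inf
  if (any(d[upper.tri(d)] == 0)) {
    # deterministic tie-jitter so nearest-neighbour sets are well defined
    message("coincident coordinates jittered deterministically for kNN")
    d <- d + matrix(seq_len(n^2) %% 97, n, n) * 1e-9
    d <- (d + t(d)) / 2
    diag(d) <- Inf
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    w[i, nb] <- 1 / k
  }
  w
}

#' Moran's I with a permutation test
#'
#' Spatial autocorrelation statistic on a row-standardized k-nearest-
#' neighbour weight matrix built from great-circle distances.  The
#' two-tailed p-value is `(1 + #{perm : |I_perm - E| >= |I_obs - E|}) /
#' (n_perm + 1)` with null expectation `E = -1/(n-1)`.
#'
#' @param values numeric response vector (non-constant).
#' @param lon,lat plot coordinates in decimal degrees.
#' @param k_neighbors number of nearest neighbours (default 5).
#' @param n_perm Monte Carlo permutations (default 999).
#' @param seed integer RNG seed.
#' @return list of class `moran_result`: `I`, `expected`, `p_perm`,
#'   `n_perm`, `k_neighbors`.
#' @export
morans_i <- function(values, lon, lat, k_neighbors = 5L, n_perm = 999L,
                     seed = 1L) {
  n <- length(values)
  stopifnot(length(lon) == n, length(lat) == n)
  if (stats::sd(values) == 0)
    stop("zero variance: Moran's I is undefined for constant values")
  w <- .knn_weights(lon, lat, k_neighbors)
  s0 <- sum(w)
  z <- values - mean(values)
  ss <- sum(z^2)
  i_obs <- (n / s0) * sum(z * (w %*% z)) / ss
  e_i <- -1 / (n - 1)
  set.seed(as.integer(seed))
  zp <- vapply(seq_len(n_perm), function(b) z[sample.int(n)],
               numeric(n))
  i_perm <- (n / s0) * colSums(zp * (w %*% zp)) / ss
  p <- (1 + sum(abs(i_perm - e_i) >= abs(i_obs - e_i))) / (n_perm + 1)
  structure(list(I = i_obs, expected = e_i, p_perm = p,
                 n_perm = as.integer(n_perm),
                 k_neighbors = as.integer(k_neighbors)),
            class = "moran_result")
}

#' Smooth elevational trend of a response
#'
#' Penalized cubic regression spline of the response on elevation
#' (Gaussian family, basis dimension k = 5 by default, smoothing parameter
#' by GCV), optionally weighted by 1/SE of the response.  The peak
#' elevation is the argmax of the fitted curve over a dense grid; it is
#' reported as `NA` ("none") when the curve is monotone at grid
#' resolution -- the maximum sits at either end of the gradient -- or
#' effectively monotone (the fitted decline beyond the argmax is at most
#' 5% of the fitted range).
#'
#' @param y numeric response.
#' @param elevation numeric vector, m a.s.l.
#' @param weights optional positive case weights (e.g. 1/SE).
#' @param k spline basis dimension (default 5).
#' @param n_grid grid size for peak location (default 500).
#' @return list of class `gam_trend`: `r2` (adjusted), `dev_expl`,
#'   `p_smooth`, `gcv`, `fitted`, `residuals`, `peak_elevation` (NA for
#'   none), `peak_strength` ("strong", "weak" or "none"), `k`, `model`.
#' @export
fit_elevation_gam <- function(y, elevation, weights = NULL, k = 5L,
                              n_grid = 500L) {
  if (any(!is.finite(y))) stop("non-finite response")
  n <- length(y)
  if (n < k + 2L) stop("too few observations for basis dimension k")
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be positive")
  dat <- data.frame(y = y, elev = elevation)
  fit <- mgcv::gam(y ~ s(elev, bs = "cr", k = k), data = dat,
                   weights = weights, method = "GCV.Cp",
                   family = stats::gaussian())
  sm <- summary(fit)
  grid <- data.frame(elev = seq(min(elevation), max(elevation),
                                length.out = n_grid))
  pred <- as.numeric(predict(fit, newdata = grid))
  imax <- which.max(pred)
  peak <- if (imax == 1L || imax == n_grid) NA_real_ else grid$elev[imax]
  # a saturating (effectively monotone) fit can show a tiny interior
  # maximum from noise; treat declines of <= 5% of the fitted range
  # beyond the argmax as "no peak"
  if (!is.na(peak)) {
    rng0 <- diff(range(pred))
    if (rng0 == 0 || (pred[imax] - min(pred[imax:n_grid])) <= 0.05 * rng0)
      peak <- NA_real_
  }
  p_smooth <- unname(sm$s.table[1L, "p-value"])
  # strength: fitted drop from peak to the upper end of the gradient must
  # exceed 10% of the fitted range, and the smooth must be significant
  strength <- "none"
  if (!is.na(peak)) {
    drop_hi <- pred[imax] - pred[n_grid]
    rng <- diff(range(pred))
    strength <- if (rng > 0 && drop_hi > 0.1 * rng && p_smooth < 0.05)
      "strong" else "weak"
  }
  structure(list(r2 = unname(sm$r.sq), dev_expl = unname(sm$dev.expl),
                 p_smooth = p_smooth, gcv = unname(fit$gcv.ubre),
                 fitted = as.numeric(fitted(fit)),
                 residuals = as.numeric(residuals(fit)),
                 peak_elevation = peak, peak_strength = strength,
                 k = as.integer(k), model = fit),
            class = "gam_trend")
}

#' Three-model decision procedure for spatial structure
#'
#' Fits Model 1 (elevation smooth only) and tests its residuals for
#' spatial autocorrelation (Moran's I, kNN weights).  If the test is
#' non-significant the baseline model stands.  Otherwise Model 2 (2-D
#' spatial smooth only) and Model 3 (elevation + 2-D spatial smooth) are
#' fitted and compared: when Model 2 explains much less variance than
#' Model 1 (`r2_m2 < theta * r2_m1`, default theta = 0.5) the spatial
#' signal is treated as a byproduct of the elevational trend and Model 1
#' is kept; otherwise Model 3 is reported with the spatial term
#' controlled.
#'
#' @param y numeric response.
#' @param elevation numeric, m a.s.l.
#' @param lon,lat plot coordinates (decimal degrees).
#' @param weights optional positive case weights.
#' @param k basis dimension of the elevation smooth (default 5).
#' @param theta "much smaller" threshold on the Model 2 / Model 1 R2
#'   ratio (default 0.5).
#' @param alpha significance level for the Moran test (default 0.05).
#' @param k_neighbors,n_perm,seed forwarded to [morans_i()].
#' @return list of class `trend_choice`: `decision` (one of "baseline",
#'   "baseline_spatial_byproduct", "spatial_controlled"), `m1` (the
#'   baseline `gam_trend`), `moran_on_m1`, and when the Moran test is
#'   significant also `r2_m1`, `r2_m2`, `r2_m3` and the chosen `model`.
#' @export
spatial_decision <- function(y, elevation, lon, lat, weights = NULL,
                             k = 5L, theta = 0.5, alpha = 0.05,
                             k_neighbors = 5L, n_perm = 999L, seed = 1L) {
  m1 <- fit_elevation_gam(y, elevation, weights = weights, k = k)
  mor <- morans_i(m1$residuals, lon, lat, k_neighbors = k_neighbors,
                  n_perm = n_perm, seed = seed)
  out <- list(m1 = m1, moran_on_m1 = mor, r2_m1 = m1$r2,
              r2_m2 = NA_real_, r2_m3 = NA_real_, theta = theta)
  if (mor$p_perm >= alpha) {
    out$decision <- "baseline"
    out$model <- m1$model
  } else {
    dat <- data.frame(y = y, elev = elevation, lon = lon, lat = lat)
    m2 <- mgcv::gam(y ~ s(lon, lat), data = dat, weights = weights,
                    method = "GCV.Cp")
    m3 <- mgcv::gam(y ~ s(elev, bs = "cr", k = k) + s(lon, lat),
                    data = dat, weights = weights, method = "GCV.Cp")
    out$r2_m2 <- unname(summary(m2)$r.sq)
    out$r2_m3 <- unname(summary(m3)$r.sq)
    if (out$r2_m2 < theta * out$r2_m1) {
      out$decision <- "baseline_spatial_byproduct"
      out$model <- m1$model
    } else {
      out$decision <- "spatial_controlled"
      out$model <- m3
    }
  }
  class(out) <- "trend_choice"
  out
}
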