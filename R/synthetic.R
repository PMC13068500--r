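# Synthetic nested-plot communities with known ground truth.
#
# The generator states a world resembling the motivating survey design:
# ~56 plots at ~20 m elevational spacing over 1960-3060 m on a mountain
# transect, four environment classes assigned by elevation band, coarse
# (~1 km) raster covariates that are smooth functions of elevation with few
# unique values, and nested occupancy across six subplot scales whose
# expected richness tracks a planted power law S(A) = c(elev) * A^z(elev).

#' Ground truth for the synthetic community generator
#'
#' @param c_fun function elevation -> c (expected richness at 1 m2);
#'   default a hump peaking at 2400 m.
#' @param z_fun function elevation -> z in (0, 1); default increases
#'   linearly from 0.05 to 0.20 across 1960-3060 m, the range reported for
#'   moss SARs on this type of gradient.
#' @param n_species size of the regional species pool (default 67).
#' @param domain elevational domain (m), default `c(1960, 3060)`.
#' @param species_ranges optional n_species x 2 matrix of elevational
#'   ranges (m); when NULL, ranges are drawn from `seed`: midpoints uniform
#'   on the domain, half-widths uniform on 100-600 m, truncated to the
#'   domain (the truncation produces the classic mid-domain overlap).
#' @param driver_spec optional named list of functions; each is applied to
#'   the matching covariate column and added to log expected richness,
#'   planting a covariate-driven signal on top of the elevational one.
#' @param seed integer seed used (only) to draw `species_ranges` when they
#'   are not supplied.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(c_fun = function(e) 2 + 6 * exp(-0.5 * ((e - 2400) / 280)^2),
                            z_fun = function(e) 0.05 + 0.15 * (e - 1960) / 1100,
                            n_species = 67L,
                            domain = c(1960, 3060),
                            species_ranges = NULL,
                            driver_spec = NULL,
                            seed = 1L) {
  if (is.null(species_ranges)) {
    set.seed(as.integer(seed))
    mid <- runif(n_species, domain[1], domain[2])
    half <- runif(n_species, 100, 600)
    species_ranges <- cbind(lo = pmax(domain[1], mid - half),
                            hi = pmin(domain[2], mid + half))
  }
  species_ranges <- as.matrix(species_ranges)
  stopifnot(ncol(species_ranges) == 2L,
            all(species_ranges[, 1] <= species_ranges[, 2]),
            all(species_ranges >= domain[1] - 1e-9),
            all(species_ranges <= domain[2] + 1e-9))
  structure(list(c_fun = c_fun, z_fun = z_fun,
                 n_species = nrow(species_ranges),
                 domain = domain, species_ranges = species_ranges,
                 driver_spec = driver_spec, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Truth parametrized by fine- and broad-scale richness profiles
#'
#' Rather than stating (c, z) directly, state the target expected richness
#' at 1 m2 (`s1_fun`) and at 100 m2 (`s100_fun`); the implied SAR
#' parameters are `c = s1` and `z = log(s100/s1) / log(100)`.  Useful for
#' planting a fine-scale mid-elevation hump together with a saturating
#' increase at the broadest scale.
#'
#' @param s1_fun,s100_fun functions elevation -> expected richness at 1 and
#'   100 m2; `s100_fun` must dominate `s1_fun` on the domain.
#' @param n_species species pool size; the default (150) is large enough
#'   that the eligible pool never caps the planted broad-scale richness
#'   near the domain edges, where range geometry thins the pool.
#' @param ... forwarded to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
truth_from_profiles <- function(s1_fun = function(e) 2 + 9 * exp(-0.5 * ((e - 2400) / 250)^2),
                                s100_fun = function(e) 45 * (1 - exp(-(e - 1500) / 1200)),
                                n_species = 150L, ...) {
  synthetic_truth(
    c_fun = s1_fun,
    z_fun = function(e) log(s100_fun(e) / s1_fun(e)) / log(100),
    n_species = n_species,
    ...
  )
}

#' Generate a synthetic plot environment table
#'
#' Plots are placed at even elevational spacing along a straight mountain
#' transect with jittered WGS84 coordinates.  Covariates are smooth
#' monotone (Bio1, Bio6, Bio7, Bio12, Bio14, WS) or unimodal (NPP, NDVI)
#' functions of elevation; with `grid_size > 0` they are evaluated at the
#' centre of the 1-km-style raster cell containing the plot, so consecutive
#' plots share values (the "limited unique values" property of coarse
#' rasters).  HD is a seeded integer habitat count in 0-4 with a weak
#' mid-elevation bulge.  Environment classes follow elevation bands:
#' grassland < 2300 m < forest < 2600 m < alpine meadow < 2850 m < alpine
#' rocky meadow.
#'
#' @param n_plots number of plots (>= 2).
#' @param elev_min,elev_max elevational span in m (default 1960-3060).
#' @param grid_size raster cell size in m along the transect (default
#'   1000); 0 disables snapping so covariates vary smoothly per plot.
#' @param seed integer RNG seed.
#' @param transect_length horizontal transect length in m (default 11000,
#'   i.e. ~200 m between neighbouring plots for 56 plots).
#' @return a `plot_table`.
#' @export
generate_environment <- function(n_plots = 56L, elev_min = 1960, elev_max = 3060,
                                 grid_size = 1000, seed = 1L,
                                 transect_length = 11000) {
  if (n_plots < 2L) stop("need at least two plots")
  span <- elev_max - elev_min
  if (span <= 0) stop("degenerate elevation span")
  set.seed(as.integer(seed))
  elev <- seq(elev_min, elev_max, length.out = n_plots)
  s <- transect_length * (elev - elev_min) / span
  # covariate source elevation: cell-centre elevation of the raster cell
  if (grid_size > 0) {
    cell <- floor(s / grid_size)
    s_c <- (cell + 0.5) * grid_size
    e_c <- pmin(elev_max, pmax(elev_min, elev_min + span * s_c / transect_length))
  } else {
    e_c <- elev
  }
  # straight NE-bearing transect from the foot of the gradient
  bearing <- 40 * pi / 180
  lat0 <- 38.95; lon0 <- 113.30
  jit <- function(n) runif(n, -30, 30)
  lat <- lat0 + (s * cos(bearing) + jit(n_plots)) / 111320
  lon <- lon0 + (s * sin(bearing) + jit(n_plots)) /
    (111320 * cos(lat0 * pi / 180))
  env_class <- cut(elev, c(-Inf, 2300, 2600, 2850, Inf),
                   labels = .environments)
  hd <- pmin(4, pmax(0, round(1.3 + 1.4 * exp(-((elev - 2350) / 400)^2) +
                                rnorm(n_plots, 0, 0.6))))
  df <- data.frame(
    plot_id = sprintf("P%02d", seq_len(n_plots)),
    lon = lon, lat = lat, elevation = elev,
    environment = as.character(env_class),
    Bio1 = 14 - 0.006 * e_c,
    Bio6 = -8 - 0.006 * e_c,
    Bio7 = 36 + 0.002 * e_c,
    Bio12 = 400 + 0.12 * e_c,
    Bio14 = 2 + 0.004 * e_c,
    WS = 1.5 + 0.001 * e_c,
    NPP = 0.25 + 0.35 * exp(-((e_c - 2400) / 350)^2),
    NDVI = 0.30 + 0.18 * exp(-((e_c - 2300) / 400)^2),
    HD = as.numeric(hd),
    stringsAsFactors = FALSE
  )
  plot_table(df)
}

#' Generate nested occurrence matrices from a stated truth
#'
#' For each plot, species are eligible iff the plot elevation falls in
#' their range.  Eligible species occupy the largest (100 m2) plot with
#' probability `p100 = min(1, S_target / n_eligible)` where
#' `S_target = c(e) * 100^z(e)` (times `exp(driver effects)` when a
#' `driver_spec` is planted, times `exp(spatial_field)` when one is
#' given).  Conditional on presence at 100 m2, a species is retained at
#' area A iff a single uniform draw falls below `(A/100)^z(e)`, so
#' occupancy is strictly nested across scales by construction and expected
#' richness at area A tracks `c(e) * A^z(e)`.
#'
#' @param plots a `plot_table`.
#' @param truth a `synthetic_truth`.
#' @param scales data.frame from [subplot_scales()].
#' @param seed integer RNG seed (defaults to `truth$seed`).
#' @param spatial_field optional per-plot numeric vector added to log
#'   expected richness, used to exercise the spatial-autocorrelation
#'   branch.
#' @return named list of `occurrence_matrix`, one per scale, smallest
#'   first; names are the areas in m2.
#' @export
generate_community <- function(plots, truth, scales = subplot_scales(),
                               seed = truth$seed, spatial_field = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  n <- nrow(plots)
  elev <- plots$elevation
  nsp <- truth$n_species
  sp_names <- sprintf("sp%03d", seq_len(nsp))
  a_max <- max(scales$area)
  if (is.null(spatial_field)) spatial_field <- numeric(n)
  # driver effects on log expected richness
  drv <- numeric(n)
  if (!is.null(truth$driver_spec)) {
    for (nm in names(truth$driver_spec))
      drv <- drv + truth$driver_spec[[nm]](plots[[nm]])
  }
  out <- lapply(scales$area, function(a)
    matrix(0L, n, nsp, dimnames = list(plots$plot_id, sp_names)))
  names(out) <- as.character(scales$area)
  zs <- truth$z_fun(elev)
  s_target <- truth$c_fun(elev) * a_max^zs * exp(drv + spatial_field)
  capped <- 0L
  for (i in seq_len(n)) {
    elig <- which(truth$species_ranges[, 1] <= elev[i] &
                    truth$species_ranges[, 2] >= elev[i])
    if (!length(elig)) next
    if (s_target[i] > length(elig)) capped <- capped + 1L
    p100 <- min(1, s_target[i] / length(elig))
    pres <- elig[runif(length(elig)) < p100]
    if (!length(pres)) next
    u <- runif(length(pres))
    for (k in seq_len(nrow(scales))) {
      keep <- pres[u <= (scales$area[k] / a_max)^zs[i]]
      if (length(keep)) out[[k]][i, keep] <- 1L
    }
  }
  if (capped > 0L)
    warning(capped, " plot(s) have fewer eligible species than the planted ",
            "expected richness; realized richness is capped by the pool")
  for (k in seq_len(nrow(scales)))
    out[[k]] <- occurrence_matrix(out[[k]], scales$area[k])
  out
}

#' Smooth isotropic spatial field over plot coordinates
#'
#' Gaussian-kernel smooth of i.i.d. noise over the plot locations; used to
#' inject spatial autocorrelation independent of elevation.
#'
#' @param plots a `plot_table`.
#' @param range_m kernel bandwidth in metres.
#' @param sd marginal standard deviation of the field.
#' @param seed integer RNG seed.
#' @return numeric vector, one value per plot, centred with sd ~ `sd`.
#' @export
smooth_spatial_field <- function(plots, range_m = 1500, sd = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  d <- haversine_matrix(plots$lon, plots$lat)
  w <- exp(-(d / range_m)^2)
  z <- as.vector(w %*% rnorm(nrow(plots)))
  z <- (z - mean(z)) / stats::sd(z)
  z * sd
}
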