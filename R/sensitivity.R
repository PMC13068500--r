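# Robustness checks on a tuned driver model: drop-one-variable refits and
# noise-perturbation refits.  Refits reuse the baseline's winning
# meta-parameters and optimal tree count rather than re-running the full
# grid, which keeps 1000 perturbation iterations tractable.

.satellite_default <- c("Bio1", "Bio6", "Bio7", "Bio12", "Bio14",
                        "WS", "NPP", "NDVI")

#' Satellite-derived predictor names
#'
#' The covariates extracted from ~1 km raster products, i.e. the set
#' subject to measurement uncertainty in the perturbation analysis.  HD
#' (field-counted) and MDE (model-derived) are excluded.
#'
#' @return character vector.
#' @export
satellite_predictors <- function() .satellite_default

# refit at the baseline's tuned meta-parameters and tree count
.refit_fixed <- function(model, X, y) {
  Xm <- .as_pred_matrix(X)
  cfg <- model$config
  fit <- .fit_brt_fixed(Xm, y, model$weights[seq_len(nrow(Xm))],
                        cfg$tree_complexity, cfg$learning_rate,
                        cfg$bag_fraction, model$n_trees_opt,
                        model$min_obs, model$step_size)
  unname(brt_performance(fit$fitted, y)["r2"])
}

#' Drop-one-variable sensitivity analysis
#'
#' Refits the model once per omitted predictor (baseline meta-parameters
#' and tree count; not a full re-grid) and compares explained variance to
#' the baseline.
#'
#' @param model a tuned `brt_model` (the baseline).
#' @param X training predictor table.
#' @param y training response.
#' @param seed integer RNG seed (bagging).
#' @return data.frame: `dropped`, `r2`, `delta_r2` (refit minus
#'   baseline); attribute `baseline_r2`.
#' @export
drop_one_analysis <- function(model, X, y, seed = 1L) {
  preds <- model$predictors
  if (length(preds) < 2L) stop("need >= 2 predictors to drop one")
  if (!all(preds %in% colnames(X)))
    stop("X lacks model predictor(s): ",
         paste(setdiff(preds, colnames(X)), collapse = ", "))
  set.seed(as.integer(seed))
  base_r2 <- unname(model$r2)
  rows <- lapply(preds, function(p) {
    r2 <- .refit_fixed(model, X[, setdiff(preds, p), drop = FALSE], y)
    data.frame(dropped = p, r2 = r2, delta_r2 = r2 - base_r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_r2") <- base_r2
  out
}

#' Noise-perturbation sensitivity analysis
#'
#' Adds independent zero-mean Gaussian noise with sd equal to
#' `noise_frac` times each column's sd to every satellite-derived
#' predictor, refits at the tuned configuration and records the explained
#' variance, repeated `n_iter` times.
#'
#' @param model a tuned `brt_model` (the baseline).
#' @param X training predictor table.
#' @param y training response.
#' @param satellite_vars predictors to perturb (default
#'   [satellite_predictors()] intersected with the model's predictors).
#' @param noise_frac noise sd as a fraction of each column sd (default
#'   0.05, i.e. "5% noise").
#' @param n_iter iterations (design default 1000; reduce for tests).
#' @param seed integer RNG seed.
#' @return list: `r2` (vector of refit r2), `summary` (mean, sd, 2.5/97.5
#'   percentiles), `baseline_r2`, `noise_frac`, `n_iter`.
#' @export
perturbation_analysis <- function(model, X, y,
                                  satellite_vars = intersect(satellite_predictors(),
                                                             model$predictors),
                                  noise_frac = 0.05, n_iter = 1000L,
                                  seed = 1L) {
  stopifnot(all(satellite_vars %in% model$predictors))
  set.seed(as.integer(seed))
  Xm <- as.data.frame(X[, model$predictors, drop = FALSE])
  sds <- vapply(Xm[satellite_vars], stats::sd, numeric(1))
  r2s <- vapply(seq_len(n_iter), function(b) {
    Xp <- Xm
    for (v in satellite_vars)
      Xp[[v]] <- Xp[[v]] + rnorm(nrow(Xp), 0, noise_frac * sds[[v]])
    .refit_fixed(model, Xp, y)
  }, numeric(1))
  list(r2 = r2s,
       summary = c(mean = mean(r2s), sd = stats::sd(r2s),
                   q025 = quantile(r2s, 0.025, names = FALSE),
                   q975 = quantile(r2s, 0.975, names = FALSE)),
       baseline_r2 = unname(model$r2),
       noise_frac = noise_frac, n_iter = as.integer(n_iter))
}
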