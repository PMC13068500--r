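# Boosted regression trees: meta-parameter tuning by 10-fold CV deviance,
# permutation-based conditional importance, partial dependence, pairwise
# interaction strength and residual spatial checks.

#' Default meta-parameter grid for BRT tuning
#'
#' The full design crosses tree complexity {1..5}, learning rate {0.0005,
#' 0.001, 0.0025, 0.005, 0.0075, 0.01, 0.025, 0.05} and bag fraction
#' {0.5, 0.55, ..., 0.9}: 5 x 8 x 9 = 360 combinations.  `reduced = TRUE`
#' gives a 12-point grid (3 x 2 x 2) for smoke runs and tests.
#'
#' @param reduced logical; return the 12-point grid instead of the full
#'   360-point one.
#' @return data.frame with columns `tree_complexity`, `learning_rate`,
#'   `bag_fraction`.
#' @export
default_brt_grid <- function(reduced = FALSE) {
  if (reduced) {
    g <- expand.grid(tree_complexity = c(1L, 2L, 3L),
                     learning_rate = c(0.005, 0.01),
                     bag_fraction = c(0.5, 0.75))
  } else {
    g <- expand.grid(tree_complexity = 1:5,
                     learning_rate = c(0.0005, 0.001, 0.0025, 0.005,
                                       0.0075, 0.01, 0.025, 0.05),
                     bag_fraction = seq(0.5, 0.9, by = 0.05))
  }
  g
}

# stratified fold assignment: blocks of K consecutive rank-ordered
# observations each contribute one observation to (almost) every fold
.make_folds <- function(n, k, strata = NULL) {
  if (is.null(strata)) return(sample(rep_len(seq_len(k), n)))
  ord <- order(strata)
  fold <- integer(n)
  blocks <- split(ord, ceiling(seq_along(ord) / k))
  for (b in blocks) fold[b] <- sample.int(k)[seq_along(b)]
  fold
}

.as_pred_matrix <- function(X) {
  m <- as.matrix(X)
  if (!is.numeric(m)) stop("predictors must be numeric")
  storage.mode(m) <- "double"
  m
}

# single boosting fit at fixed meta-parameters and tree count
.fit_brt_fixed <- function(X, y, w, tc, lr, bag, n_trees, min_obs, step_size) {
  fit <- cpp_gbm_fit(X, y, w, matrix(0, 0L, ncol(X)), as.integer(n_trees),
                     lr, as.integer(tc), bag, as.integer(min_obs),
                     as.integer(step_size), TRUE)
  fit
}

#' Tune and fit a boosted regression tree model
#'
#' For every meta-parameter combination in `grid`, forward-stagewise
#' boosting (squared-error loss) is run inside 10-fold cross-validation;
#' the CV deviance (weighted mean squared held-out error) is tracked every
#' `step_size` trees and scanning stops after it has risen for
#' `patience` consecutive checkpoints.  The optimal tree count is the CV
#' deviance minimum, the grid point with the lowest minimum wins, and the
#' final model is refit on all data at its optimal tree count.
#'
#' @param X predictor table (numeric data.frame or matrix).
#' @param y numeric response (non-constant).
#' @param weights optional positive case weights (e.g. 1/SE for SAR
#'   parameters); normalized internally to mean 1.
#' @param grid data.frame from [default_brt_grid()] (or any subset).
#' @param cv_folds number of CV folds (default 10).
#' @param strata optional numeric vector; folds are stratified by its rank
#'   (e.g. elevation) to stabilize CV on small samples.
#' @param max_trees,step_size boosting schedule (defaults 10000 and 50).
#' @param min_obs minimum observations per terminal node (default 5,
#'   suited to ~56-row tables).
#' @param patience consecutive rising checkpoints before the CV scan
#'   stops (default 5).
#' @param seed integer RNG seed (folds, bagging).
#' @return object of class `brt_model`: the fitted trees plus `config`
#'   (winning grid row), `n_trees_opt`, `cv_deviance`, `cv_correlation`,
#'   `cv_pred`, `pseudo_r2`, `rmse`, `mae`, `r2`, `fitted`, `predictors`.
#' @export
tune_brt <- function(X, y, weights = NULL, grid = default_brt_grid(),
                     cv_folds = 10L, strata = NULL, max_trees = 10000L,
                     step_size = 50L, min_obs = 5L, patience = 5L,
                     seed = 1L) {
  Xm <- .as_pred_matrix(X)
  n <- nrow(Xm)
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (n < cv_folds) stop("fewer rows than CV folds")
  if (stats::sd(y) == 0) stop("constant response: nothing to boost")
  w <- if (is.null(weights)) rep(1, n) else weights / mean(weights)
  if (any(w <= 0)) stop("weights must be positive")
  set.seed(as.integer(seed))
  fold <- .make_folds(n, cv_folds, strata = strata)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    tc <- grid$tree_complexity[g]
    lr <- grid$learning_rate[g]
    bag <- grid$bag_fraction[g]
    sse <- NULL
    cv_pred_staged <- NULL
    ck <- NULL
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      fit <- cpp_gbm_fit(Xm[tr, , drop = FALSE], y[tr], w[tr],
                         Xm[!tr, , drop = FALSE], as.integer(max_trees),
                         lr, as.integer(tc), bag, as.integer(min_obs),
                         as.integer(step_size), FALSE)
      if (is.null(sse)) {
        ck <- fit$checkpoints
        sse <- numeric(length(ck))
        cv_pred_staged <- matrix(NA_real_, n, length(ck))
      }
      err <- (fit$val_staged - y[!tr])^2 * w[!tr]
      sse <- sse + colSums(err)
      cv_pred_staged[!tr, ] <- fit$val_staged
    }
    cv_dev <- sse / sum(w)
    # scan forward, stop after `patience` consecutive checkpoints above
    # the running minimum (mirrors the stepwise forward procedure)
    run_min <- Inf; rises <- 0L; stop_at <- length(ck)
    for (i in seq_along(cv_dev)) {
      if (cv_dev[i] < run_min) { run_min <- cv_dev[i]; rises <- 0L }
      else {
        rises <- rises + 1L
        if (rises >= patience) { stop_at <- i; break }
      }
    }
    scan <- seq_len(stop_at)
    i_opt <- scan[which.min(cv_dev[scan])]
    if (is.null(best) || cv_dev[i_opt] < best$cv_deviance) {
      best <- list(grid_row = g, cv_deviance = cv_dev[i_opt],
                   n_trees_opt = ck[i_opt],
                   cv_pred = cv_pred_staged[, i_opt])
    }
  }
  cfg <- grid[best$grid_row, , drop = FALSE]
  final <- .fit_brt_fixed(Xm, y, w, cfg$tree_complexity, cfg$learning_rate,
                          cfg$bag_fraction, best$n_trees_opt, min_obs,
                          step_size)
  fitted <- final$fitted
  wm <- sum(w * y) / sum(w)
  pseudo_r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - wm)^2)
  perf <- brt_performance(fitted, y)
  structure(list(trees = final$trees, init = final$init,
                 shrinkage = cfg$learning_rate,
                 config = cfg, n_trees_opt = best$n_trees_opt,
                 cv_deviance = best$cv_deviance,
                 cv_correlation = suppressWarnings(cor(y, best$cv_pred)),
                 cv_pred = best$cv_pred,
                 pseudo_r2 = pseudo_r2,
                 rmse = perf["rmse"], mae = perf["mae"], r2 = perf["r2"],
                 fitted = fitted, y = y, weights = w,
                 min_obs = min_obs, step_size = step_size,
                 predictors = colnames(Xm)),
            class = "brt_model")
}

#' Predict from a fitted BRT model
#'
#' Predictions always use the model's optimal tree count unless `n_trees`
#' overrides it (the "pred_wrapper" contract used by the permutation
#' importance).
#'
#' @param object a `brt_model`.
#' @param newdata predictor table with the training columns.
#' @param n_trees number of trees to use (default `object$n_trees_opt`).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.brt_model <- function(object, newdata, n_trees = object$n_trees_opt,
                              ...) {
  Xm <- .as_pred_matrix(newdata[, object$predictors, drop = FALSE])
  cpp_gbm_predict(object$trees, object$init, object$shrinkage, Xm,
                  as.integer(n_trees))
}

#' Standard fit metrics on observed vs predicted values
#'
#' @param predicted,observed numeric vectors.
#' @return named vector: `rmse`, `mae`, `r2` (squared Pearson correlation
#'   convention is not used; `r2 = 1 - SSE/SST`).
#' @export
brt_performance <- function(predicted, observed) {
  e <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
    r2 = if (sst > 0) 1 - sum(e^2) / sst else NA_real_)
}

#' Permutation-based conditional variable importance
#'
#' For each predictor, the increase in RMSE when that column is randomly
#' permuted (all others fixed), averaged over `n_perm` independent
#' permutations; predictions always use the model's optimal tree count.
#' Negative mean increases are floored at 0 and the scores are normalized
#' to percentages summing to exactly 100.
#'
#' @param model a `brt_model`.
#' @param X training predictor table.
#' @param y training response.
#' @param n_perm permutations per variable (default 20).
#' @param seed integer RNG seed.
#' @return data.frame: `predictor`, `raw_rmse_increase`, `ri` (percent),
#'   sorted by decreasing `ri`.
#' @export
conditional_importance <- function(model, X, y, n_perm = 20L, seed = 1L) {
  Xm <- .as_pred_matrix(X[, model$predictors, drop = FALSE])
  set.seed(as.integer(seed))
  base_rmse <- sqrt(mean((y - predict(model, Xm))^2))
  n <- nrow(Xm)
  raw <- vapply(seq_along(model$predictors), function(j) {
    inc <- vapply(seq_len(n_perm), function(b) {
      Xp <- Xm
      Xp[, j] <- Xp[sample.int(n), j]
      sqrt(mean((y - predict(model, Xp))^2)) - base_rmse
    }, numeric(1))
    mean(inc)
  }, numeric(1))
  floored <- pmax(raw, 0)
  tot <- sum(floored)
  ri <- if (tot > 0) 100 * floored / tot else {
    warning("all permutation importances are zero; returning a uniform split")
    rep(100 / length(floored), length(floored))
  }
  out <- data.frame(predictor = model$predictors,
                    raw_rmse_increase = raw, ri = ri,
                    stringsAsFactors = FALSE)
  out[order(-out$ri), , drop = FALSE]
}

#' Partial dependence of the fitted function on one predictor
#'
#' Average prediction over the data with the focal column set to each grid
#' value, centred by subtracting the curve mean.
#'
#' @param model a `brt_model`.
#' @param X training predictor table.
#' @param predictor column name.
#' @param n_grid number of grid values over the predictor's range.
#' @return data.frame: `value`, `effect` (centred; mean exactly 0).
#' @export
partial_dependence <- function(model, X, predictor, n_grid = 50L) {
  Xm <- .as_pred_matrix(X[, model$predictors, drop = FALSE])
  j <- match(predictor, model$predictors)
  if (is.na(j)) stop("unknown predictor: ", predictor)
  grid <- seq(min(Xm[, j]), max(Xm[, j]), length.out = n_grid)
  eff <- vapply(grid, function(v) {
    Xg <- Xm; Xg[, j] <- v
    mean(predict(model, Xg))
  }, numeric(1))
  data.frame(value = grid, effect = eff - mean(eff))
}

#' Pairwise interaction strength of a fitted BRT
#'
#' Friedman-H-style statistic: for each predictor pair, the variance of
#' the two-variable partial-dependence surface left after removing both
#' one-variable partial-dependence effects, normalized by the variance of
#' the two-variable surface.  Zero for a purely additive fit.
#'
#' @param model a `brt_model` (tree complexity must exceed 1 for
#'   interactions to exist; otherwise an empty result is returned with a
#'   message).
#' @param X training predictor table.
#' @param n_grid per-axis grid size for the PD surfaces (default 10).
#' @return list: `pairs` (data.frame `var1`, `var2`, `strength`, sorted
#'   decreasing), `matrix` (symmetric, zero diagonal), `top4`.
#' @export
interaction_strength <- function(model, X, n_grid = 10L) {
  p <- length(model$predictors)
  mat <- matrix(0, p, p, dimnames = list(model$predictors, model$predictors))
  if (model$config$tree_complexity <= 1L) {
    message("tree complexity 1: no interactions by construction")
    empty <- data.frame(var1 = character(), var2 = character(),
                        strength = numeric())
    return(list(pairs = empty, matrix = mat, top4 = empty))
  }
  Xm <- .as_pred_matrix(X[, model$predictors, drop = FALSE])
  n <- nrow(Xm)
  grids <- lapply(seq_len(p), function(j) {
    u <- sort(unique(Xm[, j]))
    if (length(u) > n_grid) u <- unique(quantile(Xm[, j],
                                                 probs = seq(0, 1, length.out = n_grid),
                                                 names = FALSE))
    u
  })
  pd1 <- lapply(seq_len(p), function(j) {
    vapply(grids[[j]], function(v) {
      Xg <- Xm; Xg[, j] <- v
      mean(predict(model, Xg))
    }, numeric(1))
  })
  rows <- list()
  for (j in seq_len(p - 1L)) for (k in (j + 1L):p) {
    gj <- grids[[j]]; gk <- grids[[k]]
    combo <- expand.grid(a = gj, b = gk)
    # stacked predict: one call per pair
    Xg <- Xm[rep(seq_len(n), nrow(combo)), , drop = FALSE]
    Xg[, j] <- rep(combo$a, each = n)
    Xg[, k] <- rep(combo$b, each = n)
    pd2 <- colMeans(matrix(predict(model, Xg), n, nrow(combo)))
    pd2c <- pd2 - mean(pd2)
    f1 <- rep(pd1[[j]] - mean(pd1[[j]]), times = length(gk))
    f2 <- rep(pd1[[k]] - mean(pd1[[k]]), each = length(gj))
    den <- mean(pd2c^2)
    h2 <- if (den > 1e-12) mean((pd2c - f1 - f2)^2) / den else 0
    mat[j, k] <- mat[k, j] <- h2
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = model$predictors[j], var2 = model$predictors[k],
      strength = h2, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  pairs <- pairs[order(-pairs$strength), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, matrix = mat,
       top4 = utils::head(pairs, 4L))
}

#' Spatial autocorrelation check on BRT residuals
#'
#' Standardizes the training residuals and delegates to [morans_i()] with
#' the design defaults (k = 5 neighbours, 999 permutations, two-tailed).
#'
#' @param model a `brt_model`.
#' @param X training predictor table.
#' @param y training response.
#' @param lon,lat plot coordinates (decimal degrees).
#' @param k_neighbors,n_perm,seed forwarded to [morans_i()].
#' @return a `moran_result`.
#' @export
residual_spatial_check <- function(model, X, y, lon, lat, k_neighbors = 5L,
                                   n_perm = 999L, seed = 1L) {
  res <- y - predict(model, X)
  if (stats::sd(res) == 0)
    stop("zero variance: residuals are constant")
  morans_i(res / stats::sd(res), lon, lat, k_neighbors = k_neighbors,
           n_perm = n_perm, seed = seed)
}
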