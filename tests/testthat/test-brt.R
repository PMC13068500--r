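# small grids and tree budgets keep the boosting tests fast; the full
# 360-point design is exercised only through default_brt_grid()'s shape
tiny_grid <- data.frame(tree_complexity = c(1L, 2L),
                        learning_rate = 0.05, bag_fraction = 0.75)

brt_X <- function(n = 80, seed = 1) {
  set.seed(seed)
  data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n), x4 = runif(n))
}

test_that("the default meta-parameter grid has the documented shape", {
  g <- default_brt_grid()
  expect_equal(nrow(g), 360)
  expect_equal(nrow(unique(g)), 360)
  expect_equal(nrow(default_brt_grid(reduced = TRUE)), 12)
})

test_that("a noiseless step function is learned almost perfectly", {
  X <- brt_X(100, 2)
  y <- ifelse(X$x1 > 0.5, 3, -3)
  m <- tune_brt(X, y, grid = tiny_grid, max_trees = 500, step_size = 25,
                seed = 1)
  expect_gt(m$pseudo_r2, 0.95)
  expect_gt(m$cv_correlation, 0.95)
  expect_lte(m$n_trees_opt, 500)
})

test_that("pure noise yields ~zero cross-validated skill", {
  set.seed(5)
  r2s <- vapply(1:8, function(b) {
    X <- brt_X(60, b)
    y <- rnorm(60)
    m <- tune_brt(X, y, grid = tiny_grid, max_trees = 300, step_size = 25,
                  seed = b)
    suppressWarnings(cor(y, m$cv_pred)^2)
  }, numeric(1))
  expect_lt(median(r2s, na.rm = TRUE), 0.15)
})

test_that("performance metrics obey their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(unname(brt_performance(y, y)), c(0, 0, 1))
  p <- rep(mean(y), 4)
  perf <- brt_performance(p, y)
  expect_equal(unname(perf["r2"]), 0)
  expect_equal(unname(perf["rmse"]), sqrt(mean((y - mean(y))^2)))
  expect_error(tune_brt(brt_X(20), rep(1, 20), grid = tiny_grid), "constant")
  expect_error(tune_brt(brt_X(5), rnorm(5), grid = tiny_grid, cv_folds = 10),
               "folds")
})

test_that("permutation importance finds the planted driver and sums to 100", {
  X <- brt_X(100, 3)
  set.seed(3)
  y <- 4 * X$x2 + rnorm(100, 0, 0.3)
  m <- tune_brt(X, y, grid = tiny_grid, max_trees = 800, step_size = 50,
                seed = 2)
  imp <- conditional_importance(m, X, y, seed = 2)
  expect_equal(sum(imp$ri), 100, tolerance = 1e-9)
  expect_equal(imp$predictor[1], "x2")
  expect_gt(imp$ri[1], 50)
  expect_lt(imp$ri[imp$predictor == "x4"], 5)  # unused predictor
})

test_that("importance percentages are invariant to affine response rescaling", {
  X <- brt_X(80, 4)
  set.seed(4)
  y <- 3 * X$x1 - 2 * X$x3 + rnorm(80, 0, 0.2)
  m1 <- tune_brt(X, y, grid = tiny_grid[2, ], max_trees = 400,
                 step_size = 50, seed = 7)
  m2 <- tune_brt(X, 10 * y + 5, grid = tiny_grid[2, ], max_trees = 400,
                 step_size = 50, seed = 7)
  i1 <- conditional_importance(m1, X, y, seed = 9)
  i2 <- conditional_importance(m2, X, 10 * y + 5, seed = 9)
  expect_equal(i1$ri[order(i1$predictor)], i2$ri[order(i2$predictor)],
               tolerance = 1e-6)
})

test_that("partial dependence recovers planted shapes and centres at zero", {
  X <- brt_X(150, 6)
  set.seed(6)
  y <- 5 * X$x1 + rnorm(150, 0, 0.2)
  m <- tune_brt(X, y, grid = tiny_grid[1, ], max_trees = 800, step_size = 50,
                seed = 3)
  pd <- partial_dependence(m, X, "x1", n_grid = 25)
  expect_equal(mean(pd$effect), 0, tolerance = 1e-9)
  expect_gt(cor(pd$value, pd$effect), 0.95)        # monotone planted shape
  pd4 <- partial_dependence(m, X, "x4", n_grid = 25)
  expect_lt(diff(range(pd4$effect)), 0.2 * diff(range(pd$effect)))
  expect_error(partial_dependence(m, X, "nope"), "unknown predictor")
})

test_that("interaction strength separates additive from interacting fits", {
  X <- brt_X(150, 8)
  set.seed(8)
  y_add <- 3 * X$x1 + 3 * X$x2 + rnorm(150, 0, 0.1)
  grid2 <- data.frame(tree_complexity = 2L, learning_rate = 0.05,
                      bag_fraction = 0.75)
  m_add <- tune_brt(X, y_add, grid = grid2, max_trees = 600, step_size = 50,
                    seed = 2)
  ia <- interaction_strength(m_add, X, n_grid = 8)
  expect_true(all(diag(ia$matrix) == 0))
  expect_equal(ia$matrix, t(ia$matrix))
  y_int <- 4 * X$x1 * X$x2 + rnorm(150, 0, 0.1)
  m_int <- tune_brt(X, y_int, grid = grid2, max_trees = 600, step_size = 50,
                    seed = 2)
  ii <- interaction_strength(m_int, X, n_grid = 8)
  expect_setequal(c(ii$pairs$var1[1], ii$pairs$var2[1]), c("x1", "x2"))
  expect_gt(ii$pairs$strength[1], max(ia$pairs$strength))
  # tree complexity 1: defined empty result
  m_tc1 <- tune_brt(X, y_add, grid = tiny_grid[1, ], max_trees = 100,
                    step_size = 50, seed = 1)
  expect_message(res <- interaction_strength(m_tc1, X), "complexity 1")
  expect_equal(nrow(res$pairs), 0)
})

test_that("fits are reproducible and respect the pred_wrapper contract", {
  X <- brt_X(60, 9)
  set.seed(9)
  y <- 2 * X$x1 + rnorm(60, 0, 0.3)
  m1 <- tune_brt(X, y, grid = tiny_grid, max_trees = 300, step_size = 25,
                 seed = 5)
  m2 <- tune_brt(X, y, grid = tiny_grid, max_trees = 300, step_size = 25,
                 seed = 5)
  expect_identical(m1$fitted, m2$fitted)
  expect_identical(m1$n_trees_opt, m2$n_trees_opt)
  # default prediction uses exactly n_trees_opt trees
  expect_equal(predict(m1, X), predict(m1, X, n_trees = m1$n_trees_opt))
  expect_equal(predict(m1, X, n_trees = m1$n_trees_opt), m1$fitted,
               tolerance = 1e-9)
})

test_that("residual spatial checks behave on planted structure", {
  pl <- generate_environment(n_plots = 56, seed = 10)
  # non-spatial predictors: the residuals carry no spatial structure, so
  # the test should be non-significant in the vast majority of seeds
  X <- brt_X(56, 10)
  ps <- vapply(1:12, function(s) {
    set.seed(s)
    y <- 2 * X$x1 + rnorm(56, 0, 0.5)
    m <- tune_brt(X, y, grid = tiny_grid, max_trees = 300, step_size = 25,
                  seed = 3)
    residual_spatial_check(m, X, y, pl$lon, pl$lat, seed = 1)$p_perm
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 10 / 12)
  # inject a smooth spatial gradient into the residuals
  set.seed(10)
  y <- 2 * X$x1 + rnorm(56, 0, 0.5)
  y2 <- y + 3 * smooth_spatial_field(pl, range_m = 1200, sd = 1, seed = 4)
  m2 <- tune_brt(X, y2, grid = tiny_grid, max_trees = 50, step_size = 25,
                 seed = 3)
  bad <- residual_spatial_check(m2, X, y2, pl$lon, pl$lat, seed = 1)
  expect_lte(bad$p_perm, 0.05)
})
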