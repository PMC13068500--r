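test_that("environment table round-trips through CSV and validates", {
  pl <- generate_environment(n_plots = 12, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_environment_table(pl, path)
  back <- read_environment_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pl), tolerance = 1e-12)

  # missing column is named in the error
  df <- as.data.frame(pl)
  df$NDVI <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_error(read_environment_table(path2), "NDVI")

  # duplicate plot ids rejected
  df2 <- as.data.frame(pl)
  df2$plot_id[2] <- df2$plot_id[1]
  expect_error(plot_table(df2), "duplicate")

  # non-numeric covariate rejected with the column named
  df3 <- as.data.frame(pl)
  df3$Bio12[3] <- "high"
  expect_error(plot_table(df3), "Bio12")
})

test_that("occurrence matrices validate cells and align to the plot table", {
  pl <- toy_plot_table()
  occ <- toy_occurrence(pl, n_species = 5)
  path <- tempfile(fileext = ".csv")
  write_occurrence_matrix(occ, path)
  back <- read_occurrence_matrix(path, 10, plots = pl, what = "side")
  expect_identical(unclass(back)[, ], unclass(occ)[, ])
  expect_equal(attr(back, "area"), 100)

  # all-zero species columns survive the round trip
  m <- unclass(occ); m[, 2] <- 0L
  occ0 <- occurrence_matrix(m, 25, plots = pl)
  write_occurrence_matrix(occ0, path)
  expect_equal(colSums(read_occurrence_matrix(path, 25, what = "area"))[[2]], 0)

  # a non-binary cell is reported with its location
  m2 <- unclass(occ); m2[2, 3] <- 2L
  expect_error(occurrence_matrix(m2, 100), "T02.*sp03")

  # unknown plot id rejected
  m3 <- unclass(occ); rownames(m3)[1] <- "NOPE"
  expect_error(occurrence_matrix(m3, 100, plots = pl), "NOPE")
})

test_that("richness_by_scale is the row-sum bookkeeping it claims to be", {
  pl <- toy_plot_table(3)
  m <- diag(3); dimnames(m) <- list(pl$plot_id, c("a", "b", "c"))
  expect_equal(unname(richness_by_scale(occurrence_matrix(m, 1))), c(1, 1, 1))
  expect_equal(unname(richness_by_scale(toy_occurrence(toy_plot_table(4), 5))),
               rep(5, 4))
  # planted gradient: generator bookkeeping equals row sums
  w <- small_world(seed = 4)
  for (a in names(w$occ))
    expect_identical(richness_by_scale(w$occ[[a]]),
                     setNames(as.integer(rowSums(unclass(w$occ[[a]]))),
                              w$plots$plot_id))
})

test_that("rarefaction matches the closed-form expectation and is monotone", {
  w <- small_world(seed = 2, n_plots = 12)
  occ <- w$occ[["25"]]
  n_res <- 400
  rc <- rarefaction_curve(occ, n_resamples = n_res, seed = 9)
  exact <- rarefaction_exact(occ)
  # per-m MC standard error of the mean accumulation value
  for (m in seq_len(nrow(rc))) {
    mc_se <- sd(c(rc$ci_low[m], rc$ci_high[m])) # crude scale guard
    tol <- 3 * max(0.02, sqrt(exact$mean_richness[m]) / sqrt(n_res))
    expect_lt(abs(rc$mean_richness[m] - exact$mean_richness[m]), tol)
  }
  # monotone means for several seeds
  for (s in 1:5)
    expect_true(all(diff(rarefaction_curve(occ, 50, seed = s)$mean_richness) >= 0))
  # endpoint equals total richness with zero CI width
  total <- sum(colSums(unclass(occ)) > 0)
  expect_equal(rc$mean_richness[nrow(rc)], total)
  expect_equal(rc$ci_low[nrow(rc)], rc$ci_high[nrow(rc)])

  # degenerate: one shared species -> flat curve at 1
  pl <- toy_plot_table(5)
  one <- occurrence_matrix(matrix(1L, 5, 1, dimnames = list(pl$plot_id, "s")),
                           1)
  rf <- rarefaction_curve(one, 20, seed = 1)
  expect_true(all(rf$mean_richness == 1) && all(rf$ci_high - rf$ci_low == 0))

  expect_error(rarefaction_curve(occ, n_resamples = 0), "n_resamples")
})

test_that("nestedness checking warns on violations and passes nested data", {
  w <- small_world(seed = 6)
  expect_silent(expect_true(check_nestedness(w$occ)))
  broken <- w$occ
  m <- unclass(broken[["100"]])
  rich_small <- richness_by_scale(broken[["25"]])
  i <- which(rich_small > 0)[1]
  m[i, ] <- 0L
  broken[["100"]] <- occurrence_matrix(m, 100)
  expect_warning(check_nestedness(broken), "nested")
})
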