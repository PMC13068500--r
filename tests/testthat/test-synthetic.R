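test_that("generated environment matches the stated survey design", {
  pl <- generate_environment(n_plots = 56, seed = 3)
  expect_equal(nrow(pl), 56)
  expect_equal(diff(pl$elevation), rep(20, 55), tolerance = 1e-9)
  expect_setequal(unique(pl$environment),
                  c("grassland", "forest", "alpine meadow",
                    "alpine rocky meadow"))
  expect_true(all(pl$HD >= 0 & pl$HD <= 4))
  # coarse raster: few unique values at 1 km cells
  expect_lt(length(unique(pl$Bio1)), 56)
  # no snapping: monotone-by-construction covariates strictly monotone
  pl0 <- generate_environment(n_plots = 56, seed = 3, grid_size = 0)
  for (v in c("Bio1", "Bio6")) expect_true(all(diff(pl0[[v]]) < 0))
  for (v in c("Bio7", "Bio12", "Bio14", "WS"))
    expect_true(all(diff(pl0[[v]]) > 0))
  expect_error(generate_environment(10, elev_min = 2000, elev_max = 2000),
               "degenerate")
})

test_that("communities are nested, deterministic and pool-capped with warning", {
  w <- small_world(seed = 11)
  areas <- as.numeric(names(w$occ))
  expect_equal(areas, sort(areas))
  # nestedness for every plot/species/scale pair
  for (k in seq_len(length(w$occ) - 1))
    expect_true(all(unclass(w$occ[[k]]) <= unclass(w$occ[[k + 1]])))
  # determinism: same seed, bit-identical; different seed differs
  again <- generate_community(w$plots, w$truth, seed = 11)
  expect_identical(lapply(w$occ, unclass), lapply(again, unclass))
  other <- generate_community(w$plots, w$truth, seed = 12)
  expect_false(identical(lapply(w$occ, unclass), lapply(other, unclass)))
  # a pool too small for the planted richness warns
  tiny <- synthetic_truth(n_species = 5, c_fun = function(e) rep(20, length(e)),
                          z_fun = function(e) rep(0.1, length(e)), seed = 1)
  expect_warning(generate_community(w$plots, tiny, seed = 1), "capped")
})

test_that("single full-range certain species is present everywhere", {
  pl <- toy_plot_table(6)
  tr <- synthetic_truth(c_fun = function(e) rep(100, length(e)),
                        z_fun = function(e) rep(1e-9, length(e)),
                        domain = c(1900, 3100),
                        species_ranges = matrix(c(1900, 3100), 1, 2),
                        seed = 1)
  # the pool-cap warning is expected: occupancy probability is pinned at 1
  occ <- suppressWarnings(generate_community(pl, tr, seed = 1))
  for (a in names(occ)) expect_true(all(unclass(occ[[a]]) == 1L))
})

test_that("SAR refits recover the planted (c, z) surfaces", {
  # constant truth over many plots: average refit close to truth
  pl <- generate_environment(n_plots = 500, seed = 21)
  tr <- synthetic_truth(c_fun = function(e) rep(4, length(e)),
                        z_fun = function(e) rep(0.25, length(e)),
                        n_species = 200, seed = 21)
  occ <- generate_community(pl, tr, seed = 21)
  sar <- fit_all_plots(occ, pl)
  expect_gt(nrow(sar), 400)
  expect_lt(abs(mean(sar$z) - 0.25), 0.03)
  # increasing z surface shows up as a positive elevation trend
  w <- generate_community(generate_environment(n_plots = 56, seed = 5),
                          synthetic_truth(seed = 5), seed = 5)
  pl56 <- generate_environment(n_plots = 56, seed = 5)
  sar56 <- fit_all_plots(w, pl56)
  expect_gt(cor(sar56$z, sar56$elevation, method = "spearman"), 0.5)
})
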