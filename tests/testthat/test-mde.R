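test_that("range extraction interpolates min-max occupied bands", {
  pl <- toy_plot_table(10)
  m <- matrix(0L, 10, 3, dimnames = list(pl$plot_id, c("a", "b", "c")))
  m[7, "a"] <- 1L                  # single band
  m[c(3, 9), "b"] <- 1L            # gap interpolated
  occ <- occurrence_matrix(m, 1, plots = pl)
  rs <- suppressMessages(extract_ranges(occ, pl))
  expect_equal(rs$species, c("a", "b"))     # empty species dropped
  expect_equal(rs$lo, c(7, 3))
  expect_equal(rs$hi, c(7, 9))
  expect_equal(rs$size, c(1, 7))
})

test_that("brute-force oracle reproduces hand-computed coverage", {
  expect_equal(brute_force_mde(range_set(2, 3))$expected, c(0.5, 1, 0.5))
  expect_equal(brute_force_mde(range_set(1, 5))$expected, rep(0.2, 5))
  # full-range species always covers everything
  expect_equal(brute_force_mde(range_set(c(5, 5, 5), 5))$expected, rep(3, 5))
})

test_that("forced placements give exact expectations with zero CI width", {
  r <- simulate_mde(range_set(4, 4), n_sims = 500, seed = 2)
  expect_equal(r$expected, rep(1, 4))
  expect_equal(r$ci_low, r$ci_high)
  r3 <- simulate_mde(range_set(c(6, 6, 6), 6), n_sims = 200, seed = 2)
  expect_equal(r3$expected, rep(3, 6))
})

test_that("Monte Carlo agrees with the exact oracle on random instances", {
  set.seed(123)
  n_sims <- 20000
  n_bands <- 0L; n_beyond3 <- 0L
  for (rep in 1:20) {
    D <- sample(3:12, 1)
    sizes <- sample.int(D, sample(1:6, 1), replace = TRUE)
    rs <- range_set(sizes, D)
    ex <- brute_force_mde(rs)$expected
    mc <- simulate_mde(rs, n_sims = n_sims, seed = rep)
    # per-band binomial-sum MC standard error
    se <- sqrt(vapply(seq_len(D), function(b) {
      p <- vapply(sizes, function(r) {
        min(b, D - r + 1) - max(1, b - r + 1) + 1
      }, numeric(1)) / (D - sizes + 1)
      sum(p * (1 - p))
    }, numeric(1)) / n_sims)
    z <- abs(mc$expected - ex) / pmax(se, 1e-300)
    z <- z[se > 0]
    # at 3 MC standard errors ~0.27% of correct bands land outside by
    # chance; gross deviations (5 SE) would indicate a real bug and are
    # never tolerated
    n_bands <- n_bands + length(z)
    n_beyond3 <- n_beyond3 + sum(z > 3)
    expect_true(all(z <= 5),
                info = sprintf("rep %d: D=%d sizes=%s", rep, D,
                               paste(sizes, collapse = ",")))
    # conservation to 1e-9 on the mean, exact per simulation by design
    expect_lt(abs(sum(mc$expected) - sum(sizes)), 1e-9)
    # symmetry of the exact expectation about the midpoint
    expect_equal(ex, rev(ex), tolerance = 1e-12)
  }
  # the count of 3-SE exceedances in a correct simulator is ~Poisson with
  # rate 2*pnorm(-3) per band; reject only beyond its 99.9% quantile
  expect_lte(n_beyond3, qpois(0.999, 2 * pnorm(-3) * n_bands))
})

test_that("mid-domain peak and reproducibility hold", {
  rs <- range_set(c(2, 5, 9, 3), 10)
  ex <- brute_force_mde(rs)$expected
  expect_gt(max(ex[4:7]), max(ex[c(1, 10)]))  # interior exceeds edges
  a <- simulate_mde(rs, 5000, seed = 42)
  b <- simulate_mde(rs, 5000, seed = 42)
  expect_identical(a, b)
  expect_error(simulate_mde(range_set(integer(0), 5), 10), "empty")
})

test_that("per-scale MDE predictors line up with the plot table", {
  w <- small_world(seed = 3)
  res <- suppressMessages(mde_by_scale(w$occ, w$plots, n_sims = 2000, seed = 1))
  expect_setequal(names(res), names(w$occ))
  for (a in names(res))
    expect_identical(res[[a]]$plot_id, w$plots$plot_id)
})
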