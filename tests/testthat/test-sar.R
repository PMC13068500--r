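areas6 <- subplot_scales()$area

test_that("exact power-law data is recovered exactly", {
  fit <- fit_power_sar(areas6, 4 * areas6^0.5)
  expect_equal(fit$c, 4, tolerance = 1e-9)
  expect_equal(fit$z, 0.5, tolerance = 1e-9)
  expect_true(fit$converged)
  # agreement with an independent log-log OLS computation
  ll <- lm(log(4 * areas6^0.5) ~ log(areas6))
  expect_equal(fit$z, unname(coef(ll)[2]), tolerance = 1e-6)
  expect_equal(fit$c, exp(unname(coef(ll)[1])), tolerance = 1e-6)
})

test_that("flat accumulation curves give z = 0 and are flagged", {
  fit <- fit_power_sar(areas6, rep(5, 6))
  expect_equal(fit$c, 5, tolerance = 1e-9)
  expect_equal(fit$z, 0, tolerance = 1e-9)
  expect_true(fit$z_flagged || fit$z == 0)
})

test_that("degenerate inputs raise the contract errors", {
  expect_error(fit_power_sar(areas6, rep(0, 6)), "all-zero")
  expect_error(fit_power_sar(c(1, 1, 1), c(1, 2, 3)), "distinct areas")
  expect_warning(fit_power_sar(areas6, c(1, 5, 4, 6, 8, 9)), "Type I")
})

test_that("noisy replicates recover the generating parameters", {
  set.seed(77)
  est <- t(replicate(200, {
    s <- pmax(0, 10 * areas6^0.15 + rnorm(6, 0, 0.5))
    f <- suppressWarnings(fit_power_sar(areas6, s))
    c(f$c, f$z, f$se_z)
  }))
  expect_lt(abs(mean(est[, 2]) - 0.15), 0.02)
  expect_lt(abs(mean(est[, 1]) / 10 - 1), 0.05)
  # SEs shrink with noise
  est_lo <- t(replicate(100, {
    s <- pmax(0, 10 * areas6^0.15 + rnorm(6, 0, 0.1))
    f <- suppressWarnings(fit_power_sar(areas6, s))
    c(f$se_z)
  }))
  expect_lt(mean(est_lo), mean(est[, 3]))
})

test_that("area rescaling is absorbed by c exactly as k^-z", {
  set.seed(3)
  s <- 6 * areas6^0.2 + rnorm(6, 0, 0.2)
  f1 <- suppressWarnings(fit_power_sar(areas6, s))
  f2 <- suppressWarnings(fit_power_sar(areas6 * 10, s))
  expect_equal(f2$z, f1$z, tolerance = 1e-6)
  expect_equal(f2$c, f1$c * 10^(-f1$z), tolerance = 1e-6)
})

test_that("fit_all_plots flags flat plots and drops unfittable ones", {
  pl <- toy_plot_table(3)
  occ <- lapply(areas6, function(a) {
    m <- matrix(0L, 3, 4, dimnames = list(pl$plot_id, paste0("s", 1:4)))
    m[1, 1:2] <- 1L            # flat curve: same 2 species at all scales
    if (a >= 25) m[2, 1:3] <- 1L  # steps up late
    occurrence_matrix(m, a)
  })
  fits <- suppressWarnings(fit_all_plots(occ, pl))
  expect_true("T01" %in% fits$plot_id)
  f1 <- fits[fits$plot_id == "T01", ]
  expect_equal(f1$z, 0, tolerance = 1e-9)
  expect_false("T03" %in% fits$plot_id)  # all-zero plot dropped
})

test_that("environment comparisons are Welch tests with Holm adjustment", {
  set.seed(10)
  fits <- data.frame(
    plot_id = sprintf("P%02d", 1:28),
    environment = rep(c("grassland", "forest"), each = 14),
    c = c(rnorm(14, 5), rnorm(14, 5)),
    z = c(rnorm(14, 0.10, 0.02), rnorm(14, 0.15, 0.02)))
  res <- compare_environments(fits)
  expect_setequal(unique(res$parameter), c("c", "z"))
  zrow <- res[res$parameter == "z", ]
  # planted +0.05 shift at n = 14/group is detectable
  expect_lt(zrow$p, 0.05)
  # identical groups give t = 0, p = 1
  same <- fits; same$c <- rep(1, 28); same$z <- rep(2, 28)
  res2 <- compare_environments(same)
  expect_true(all(res2$t == 0) && all(res2$p == 1))
  # independent oracle: plain Welch t-test on the same split (group1 is
  # the alphabetically first environment, i.e. forest)
  tt <- t.test(fits$z[15:28], fits$z[1:14])
  expect_equal(zrow$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(zrow$p, tt$p.value, tolerance = 1e-12)
  # under-sized groups are excluded with a warning
  fits$environment[1] <- "alpine meadow"
  expect_warning(compare_environments(fits), "alpine meadow")
})
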