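test_that("bland_altman matches hand computation on a tiny example", {
  # diffs 1, -1, 1, -1: mean 0, sd = sqrt(4/3)
  a <- c(11, 9, 11, 9); b <- c(10, 10, 10, 10)
  r <- bland_altman(a, b)
  expect_equal(r$mean_diff, 0)
  expect_equal(r$sd_diff, sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(r$sd_diff, 1.1547, tolerance = 1e-4)
  expect_equal(r$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-9)
  expect_equal(r$loa_high, 2.2632, tolerance = 1e-4)
  expect_equal(r$loa_low, -r$loa_high, tolerance = 1e-12)
  # identical methods: all zeros
  z <- bland_altman(a, a)
  expect_equal(z$mean_diff, 0)
  expect_equal(z$sd_diff, 0)
  expect_equal(c(z$loa_low, z$loa_high), c(0, 0))
  expect_error(bland_altman(1:5, 1:4), class = "input_error")
  expect_error(bland_altman(1:2, 1:2), class = "input_error")
})

test_that("bland_altman invariants: LoA symmetry and argument mirroring", {
  set.seed(11)
  a <- rnorm(30, 65, 10); b <- a + rnorm(30, 0.5, 2)
  r <- bland_altman(a, b)
  expect_equal(r$loa_high - r$mean_diff, r$mean_diff - r$loa_low,
               tolerance = 1e-12)
  expect_equal(r$loa_high - r$mean_diff, r$multiplier * r$sd_diff,
               tolerance = 1e-12)
  m <- bland_altman(b, a)
  expect_equal(m$mean_diff, -r$mean_diff, tolerance = 1e-12)
  expect_equal(m$sd_diff, r$sd_diff, tolerance = 1e-12)
  expect_equal(m$loa_low, -r$loa_high, tolerance = 1e-12)
  expect_equal(m$loa_high, -r$loa_low, tolerance = 1e-12)
  # CIs contain their point estimates
  expect_true(r$ci_mean[1] <= r$mean_diff && r$mean_diff <= r$ci_mean[2])
  expect_true(r$ci_loa_low[1] <= r$loa_low && r$loa_low <= r$ci_loa_low[2])
  expect_true(r$ci_loa_high[1] <= r$loa_high &&
                r$loa_high <= r$ci_loa_high[2])
})

test_that("limits of agreement from published summary statistics", {
  # body-volume agreement table: mean 0.1670, SD 3.7504
  bv <- loa_from_summary(0.1670, 3.7504)
  expect_equal(unname(bv["loa_high"]), 7.5176, tolerance = 1e-3)
  # fat-mass agreement table: mean -0.2911, SD 6.3625
  fm <- loa_from_summary(-0.2911, 6.3625)
  expect_equal(unname(fm["loa_low"]), -12.7613, tolerance = 1e-3)
  expect_equal(unname(fm["loa_high"]), 12.1791, tolerance = 1e-3)
  expect_equal(unname(loa_from_summary(0, 1)), c(-1.96, 1.96))
  expect_error(loa_from_summary(0, -1), class = "domain_error")
})

test_that("ICC handles the exact and degenerate cases", {
  # raters identical, subjects vary: perfect agreement
  x <- cbind(1:6, 1:6, 1:6)
  r <- icc(x)
  expect_equal(r$icc_value, 1, tolerance = 1e-12)
  # no subject variance beyond rater noise: non-positive ICC with warning
  y <- 5 + cbind(c(0, 1, 0, 1, 0, 1), c(1, 0, 1, 0, 1, 0))
  expect_warning(r2 <- icc(y), class = "degenerate_icc")
  expect_lte(r2$icc_value, 0)
  expect_error(icc(matrix(3, 5, 2)), class = "undefined_icc")
  expect_error(icc(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)),
               class = "not_supported")
  expect_error(icc(matrix(1:4, 2, 2)), class = "input_error")
})

test_that("ICC matches the from-scratch ANOVA oracle on random grids", {
  set.seed(202)
  for (i in 1:100) {
    g <- matrix(rnorm(15, mean = rep(rnorm(5, 60, 8), 3), sd = 1), 5, 3)
    r21 <- icc(g, form = "ICC(2,1)")
    expect_equal(r21$icc_value, icc21_oracle(g), tolerance = 1e-9)
    r31 <- icc(g, form = "ICC(3,1)")
    expect_equal(r31$icc_value, icc31_oracle(g), tolerance = 1e-9)
    expect_true(r21$ci[1] <= r21$icc_value && r21$icc_value <= r21$ci[2])
    expect_true(r31$ci[1] <= r31$icc_value && r31$icc_value <= r31$ci[2])
  }
})

test_that("ICC is invariant to shifting and positive rescaling", {
  set.seed(17)
  g <- matrix(rnorm(24, rep(rnorm(8, 50, 5), 3), 1), 8, 3)
  base <- icc(g)$icc_value
  expect_equal(icc(g + 100)$icc_value, base, tolerance = 1e-9)
  expect_equal(icc(g * 3.7)$icc_value, base, tolerance = 1e-9)
  expect_equal(icc(g * 3.7 + 100)$icc_value, base, tolerance = 1e-9)
})

test_that("coefficient of variation is SD over mean", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-9)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.7071, tolerance = 1e-4)
  set.seed(23)
  v <- rnorm(200, 66.5, 13.03)
  expect_equal(coefficient_of_variation(v), sd(v) / mean(v),
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), class = "undefined_error")
})

test_that("bland-altman plot writes a figure with the three reference lines", {
  set.seed(31)
  a <- rnorm(20, 65, 8); b <- a + rnorm(20, 0, 2)
  r <- bland_altman(a, b)
  p <- autoplot(r)
  expect_s3_class(p, "ggplot")
  f <- withr::local_tempfile(fileext = ".png")
  bland_altman_plot(r, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  # layer data carry the bias and LoA intercepts
  yints <- unlist(lapply(ggplot2::ggplot_build(p)$data,
                         function(d) d$yintercept))
  expect_true(any(abs(yints - r$mean_diff) < 1e-12))
  expect_true(any(abs(yints - r$loa_low) < 1e-12))
  expect_true(any(abs(yints - r$loa_high) < 1e-12))
  expect_error(bland_altman_plot(r, pairs = r$pairs[0, ]),
               class = "input_error")
})

test_that("tidy and glance methods return the reported quantities", {
  set.seed(5)
  a <- rnorm(15, 60, 5); b <- a + rnorm(15)
  r <- bland_altman(a, b)
  td <- tidy(r)
  expect_setequal(td$term, c("mean_diff", "sd_diff", "loa_low", "loa_high"))
  expect_equal(td$estimate[td$term == "mean_diff"], r$mean_diff)
  gl <- glance(r)
  expect_equal(gl$n, 15)
  cal <- fit_bv_calibration(a, b)
  expect_equal(glance(cal)$slope, cal$slope)
  expect_equal(nrow(tidy(cal)), 2)
  ic <- icc(cbind(a, b))
  expect_equal(tidy(ic)$estimate, ic$icc_value)
})
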