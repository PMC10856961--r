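test_that("replicate selection applies the 150 mL / 0.3% protocol", {
  r <- select_replicates(c(62.00, 62.10))
  expect_equal(r$selected_value, 62.05)
  expect_equal(r$selected_pair, c(1L, 2L))
  expect_error(select_replicates(c(62.00, 62.40)),
               class = "needs_third_measurement")
  # 0.3% of the mean can exceed 150 mL for large volumes
  expect_equal(select_replicates(c(100.0, 100.25))$selected_value, 100.125)
  r3 <- select_replicates(c(62.00, 62.40, 62.10))
  expect_equal(r3$selected_value, 62.05)
  expect_equal(r3$selected_pair, c(1L, 3L))
})

test_that("replicate selection matches the pairwise brute-force oracle and is
           permutation-stable", {
  set.seed(101)
  for (i in 1:1000) {
    v <- round(rnorm(3, 65, 1.5), 3)
    expect_equal(select_replicates(v)$selected_value,
                 select_replicates_oracle(v))
  }
  set.seed(102)
  for (i in 1:50) {
    v <- round(rnorm(4, 65, 1), 3)
    base <- select_replicates(v)$selected_value
    for (j in 1:5) {
      p <- sample(v)
      expect_equal(select_replicates(p)$selected_value,
                   select_replicates_oracle(p))
    }
    expect_equal(base, select_replicates_oracle(v))
  }
})

test_that("body density and the Siri equation follow their closed forms", {
  expect_equal(body_density(66, 60), 1.1)
  expect_equal(body_density(70, 70), 1.0)
  expect_equal(body_density(78.1, 69.7), 78.1 / 69.7, tolerance = 1e-12)
  expect_error(body_density(-1, 60), class = "domain_error")
  expect_equal(siri_percent_fat(1.1), 0)
  expect_equal(siri_percent_fat(1.0), 45)
  expect_equal(siri_percent_fat(0.99), 50, tolerance = 1e-12)
  expect_warning(siri_percent_fat(0.85), class = "out_of_domain")
  expect_error(siri_percent_fat(-0.1), class = "domain_error")
  # strictly decreasing in density
  d <- seq(0.95, 1.14, by = 0.01)
  expect_true(all(diff(siri_percent_fat(d)) < 0))
})

test_that("volume calibration recovers exact and noisy linear relations", {
  raw <- c(60, 65, 70, 75, 80)
  m_id <- fit_bv_calibration(raw, raw)
  expect_equal(m_id$slope, 1, tolerance = 1e-12)
  expect_equal(m_id$intercept, 0, tolerance = 1e-9)
  expect_equal(m_id$residual_sd, 0, tolerance = 1e-9)
  ref <- 0.9 * raw + 2
  m_lin <- fit_bv_calibration(raw, ref)
  expect_equal(m_lin$slope, 0.9, tolerance = 1e-9)
  expect_equal(m_lin$intercept, 2, tolerance = 1e-9)
  expect_equal(apply_calibration(m_lin, 70), 65, tolerance = 1e-9)
  expect_equal(apply_calibration(m_lin, raw), ref, tolerance = 1e-9)
  # noisy recovery within 3 standard errors
  set.seed(7)
  raw_n <- runif(50, 50, 90)
  ref_n <- 0.93 * raw_n + rnorm(50, sd = 1)
  m_n <- fit_bv_calibration(raw_n, ref_n)
  se <- summary(m_n$fit)$coefficients["raw_bv", 2]
  expect_lt(abs(m_n$slope - 0.93), 3 * se)
  # OLS property: fitted mean equals reference mean on the fitting set
  expect_equal(mean(apply_calibration(m_n, raw_n)), mean(ref_n),
               tolerance = 1e-9)
  expect_error(fit_bv_calibration(rep(70, 5), raw), class = "singular_fit")
  expect_error(fit_bv_calibration(1:4, 1:5), class = "shape_error")
})

test_that("the fat-mass equation evaluates and stays linear", {
  s_m <- subject_record(2, 30, 1.72, 78.1, 150)
  expect_equal(fat_mass_eq1(s_m, 69.7)$fm_kg,
               42.5 - 5.73 * 2 - 0.02254 * 150 - 26.3 * 1.72 + 0.4879 * 69.7,
               tolerance = 1e-12)
  expect_equal(fat_mass_eq1(s_m, 69.7)$fm_kg, 16.42963, tolerance = 1e-5)
  s_f <- subject_record(1, 30, 1.60, 61, 0)
  expect_equal(fat_mass_eq1(s_f, 60.7)$fm_kg, 24.30553, tolerance = 1e-5)
  expect_error(fat_mass_eq1(list(sex_code = 3, pa_min_week = 0,
                                 height_m = 1.7), 60),
               class = "coding_error")
  # linearity: doubling a covariate delta doubles the response delta
  base <- fat_mass_eq1(s_m, 60)$fm_kg
  d1 <- fat_mass_eq1(s_m, 62)$fm_kg - base
  d2 <- fat_mass_eq1(s_m, 64)$fm_kg - base
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
  pa1 <- fat_mass_eq1(subject_record(2, 30, 1.72, 78.1, 250), 60)$fm_kg - base
  pa2 <- fat_mass_eq1(subject_record(2, 30, 1.72, 78.1, 350), 60)$fm_kg - base
  expect_equal(pa2, 2 * pa1, tolerance = 1e-9)
})

test_that("subject records validate and derive BMI", {
  s <- subject_record(1, 25, 1.6, 64, 100)
  expect_equal(s$bmi_kg_m2, 64 / 1.6^2, tolerance = 1e-9)
  expect_warning(subject_record(2, 25, 1.96, 80, 0), class = "out_of_domain")
  expect_warning(subject_record(2, 25, 1.8, 140, 0), class = "out_of_domain")
  expect_error(subject_record(0, 25, 1.8, 80, 0), class = "coding_error")
})

test_that("bv error report returns mean differences on both scales", {
  r <- report_bv_error(72.31, 67.03)
  expect_equal(r$absolute_error_l, 5.28, tolerance = 1e-9)
  expect_equal(r$percent_error, 5.28 / 67.03 * 100, tolerance = 1e-9)
  same <- report_bv_error(c(60, 70), c(60, 70))
  expect_equal(same$absolute_error_l, 0)
  expect_equal(same$percent_error, 0)
  single <- report_bv_error(61, 60)
  expect_equal(single$absolute_error_l, 1, tolerance = 1e-12)
  expect_equal(single$percent_error, 100 / 60, tolerance = 1e-9)
  expect_error(report_bv_error(1:3, 1:2), class = "shape_error")
})
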