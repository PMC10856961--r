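#' Subject covariate record
#'
#' Covariates feeding the fat-mass regression: sex code (1 = female,
#' 2 = male), age, height, weight and weekly physical-activity minutes.
#' Height and weight outside the study's inclusion bounds
#' (height <= 1.94 m, weight <= 136 kg, and sensible lower bounds) raise
#' a warning, not an error. BMI is derived as `weight / height^2`.
#'
#' @param sex_code 1 (female) or 2 (male).
#' @param age_years Age in years.
#' @param height_m Height in metres.
#' @param weight_kg Weight in kilograms.
#' @param pa_min_week Physical activity, minutes per week (>= 0).
#' @return A one-row tibble of class `subject_record` including
#'   `bmi_kg_m2`.
#' @export
subject_record <- function(sex_code, age_years, height_m, weight_kg,
                           pa_min_week) {
  if (!sex_code %in% c(1, 2))
    stop_bodyscan("coding_error", "sex_code must be 1 (female) or 2 (male)")
  stopifnot(height_m > 0, weight_kg > 0, pa_min_week >= 0)
  if (height_m <= 0.5 || height_m > 1.94)
    warn_bodyscan("out_of_domain",
                  "height outside the (0.5, 1.94] m inclusion bounds")
  if (weight_kg <= 20 || weight_kg > 136)
    warn_bodyscan("out_of_domain",
                  "weight outside the (20, 136] kg inclusion bounds")
  out <- tibble::tibble(
    sex_code = as.integer(sex_code), age_years = age_years,
    height_m = height_m, weight_kg = weight_kg,
    pa_min_week = pa_min_week, bmi_kg_m2 = weight_kg / height_m^2
  )
  class(out) <- c("subject_record", class(out))
  out
}

#' Select the replicate pair of body-volume measurements
#'
#' Implements the air-displacement-plethysmography replicate protocol:
#' body volume is measured at least twice; if the first two measurements
#' differ by more than 150 mL or 0.3 percent (of the pair mean), a third
#' measurement is required, and the average of the two closest values is
#' used. With three or more values the closest pair is always used (ties:
#' the pair whose mean is nearest the overall median, then the
#' earliest-index pair).
#'
#' @param values Numeric vector (>= 2) of replicate volumes in litres.
#' @return A list of class `replicate_set`: `bv_liters`, `selected_pair`
#'   (indices) and `selected_value` (their mean, litres). Two discordant
#'   values without a third raise `needs_third_measurement`.
#' @examples
#' select_replicates(c(62.00, 62.10))$selected_value  # 62.05
#' @export
select_replicates <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (length(values) == 2) {
    tol <- max(0.150, 0.003 * mean(values[1:2]))
    if (abs(values[1] - values[2]) > tol)
      stop_bodyscan("needs_third_measurement",
                    sprintf(paste0("first two replicates differ by %.3f L ",
                                   "(tolerance %.3f L): a third measurement ",
                                   "is required"),
                            abs(values[1] - values[2]), tol))
    pair <- c(1L, 2L)
  } else {
    pairs <- utils::combn(length(values), 2)
    diffs <- abs(values[pairs[1, ]] - values[pairs[2, ]])
    best <- which(diffs == min(diffs))
    if (length(best) > 1) {
      means <- (values[pairs[1, best]] + values[pairs[2, best]]) / 2
      dmed <- abs(means - stats::median(values))
      best <- best[dmed == min(dmed)]
    }
    pair <- pairs[, best[1]]           # combn order = earliest-index pair
  }
  structure(list(bv_liters = values, selected_pair = pair,
                 selected_value = mean(values[pair])),
            class = "replicate_set")
}

#' Whole-body density
#'
#' Body mass divided by (thoracic-gas-corrected) body volume.
#'
#' @param weight_kg Body mass in kg (> 0).
#' @param corrected_bv_liters Body volume in litres (> 0).
#' @return Density in kg/L.
#' @export
body_density <- function(weight_kg, corrected_bv_liters) {
  if (any(weight_kg <= 0) || any(corrected_bv_liters <= 0))
    stop_bodyscan("domain_error", "weight and volume must be positive")
  weight_kg / corrected_bv_liters
}

#' Percent body fat from density (two-compartment Siri equation)
#'
#' `BF\% = 495 / density - 450` with the standard Siri constants
#' (configurable). Densities outside the physiological band (0.9, 1.15)
#' kg/L raise a warning.
#'
#' @param density_kg_L Whole-body density in kg/L.
#' @param c1,c2 Siri constants (defaults 495 and 450).
#' @return Percent body fat.
#' @examples
#' siri_percent_fat(1.1)  # 0
#' @export
siri_percent_fat <- function(density_kg_L, c1 = 495, c2 = 450) {
  if (any(density_kg_L <= 0))
    stop_bodyscan("domain_error", "density must be positive")
  if (any(density_kg_L <= 0.9 | density_kg_L >= 1.15))
    warn_bodyscan("out_of_domain",
                  "density outside the physiological band (0.9, 1.15) kg/L")
  c1 / density_kg_L - c2
}

#' Calibrate raw depth-camera volumes against a reference
#'
#' Ordinary least squares of the reference volumes on the raw
#' reconstructed volumes. The fitted ("calibrated") volumes have zero
#' mean residual on the fitting set by construction; the systematic
#' overestimate of the two-view reconstruction (lateral in-fill) is
#' absorbed here.
#'
#' @param raw_bv,reference_bv Equal-length numeric vectors (n >= 3),
#'   litres.
#' @return An object of class `bv_calibration`: `slope`, `intercept`,
#'   `n_fit`, `residual_sd` and the underlying `lm` fit.
#' @export
fit_bv_calibration <- function(raw_bv, reference_bv) {
  if (length(raw_bv) != length(reference_bv))
    stop_bodyscan("shape_error", "raw and reference lengths differ")
  stopifnot(length(raw_bv) >= 3)
  if (stats::sd(raw_bv) < 1e-12)
    stop_bodyscan("singular_fit", "raw volumes are constant: cannot calibrate")
  fit <- stats::lm(reference_bv ~ raw_bv,
                   data = data.frame(raw_bv = raw_bv,
                                     reference_bv = reference_bv))
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n_fit = length(raw_bv),
         # suppressed: "essentially perfect fit" on exact linear input
         residual_sd = suppressWarnings(summary(fit)$sigma),
         fit = fit),
    class = "bv_calibration"
  )
}

#' @rdname fit_bv_calibration
#' @param model A `bv_calibration`.
#' @param raw_liters Raw volume(s) to calibrate.
#' @return `apply_calibration`: fitted volume(s) in litres.
#' @export
apply_calibration <- function(model, raw_liters) {
  stopifnot(inherits(model, "bv_calibration"))
  model$slope * raw_liters + model$intercept
}

#' @export
print.bv_calibration <- function(x, ...) {
  cat(sprintf(
    "<bv_calibration> fitted = %.4f * raw %+0.4f L (n = %d, residual SD %.3f L)\n",
    x$slope, x$intercept, x$n_fit, x$residual_sd))
  invisible(x)
}

# published fat-mass regression coefficients (kg; sex 1 = F, 2 = M;
# physical activity in min/week; height in m; calibrated BV in L)
fm_default_coefs <- c(intercept = 42.5, sex = -5.73, pa = -0.02254,
                      height = -26.3, bv = 0.4879)

#' Fat mass from covariates and calibrated body volume
#'
#' Evaluates the fat-mass regression
#' `FM = 42.5 - 5.73 sex - 0.02254 PA - 26.3 height + 0.4879 BV`
#' (kg; sex coded 1 for women, 2 for men; PA in minutes/week; height in
#' metres; BV the calibrated body volume in litres). Negative predictions
#' are returned with an out-of-domain warning.
#'
#' @param subject A [subject_record()] (or any list/row with `sex_code`,
#'   `pa_min_week`, `height_m`).
#' @param fitted_bv_liters Calibrated body volume in litres.
#' @param coefs Named coefficient vector (override to re-fit the model).
#' @return An object of class `fm_estimate`: `fm_kg` plus an echo of the
#'   inputs from which it can be recomputed exactly.
#' @examples
#' s <- subject_record(2, 30, 1.72, 78, 150)
#' fat_mass_eq1(s, 69.7)$fm_kg
#' @export
fat_mass_eq1 <- function(subject, fitted_bv_liters,
                         coefs = fm_default_coefs) {
  sex <- subject$sex_code
  if (!all(sex %in% c(1, 2)))
    stop_bodyscan("coding_error", "sex_code must be 1 (female) or 2 (male)")
  pa <- subject$pa_min_week
  h <- subject$height_m
  stopifnot(all(pa >= 0), all(h > 0), all(fitted_bv_liters > 0))
  fm <- coefs[["intercept"]] + coefs[["sex"]] * sex + coefs[["pa"]] * pa +
    coefs[["height"]] * h + coefs[["bv"]] * fitted_bv_liters
  if (any(fm < 0))
    warn_bodyscan("out_of_domain", "negative fat-mass prediction")
  structure(
    list(fm_kg = fm,
         inputs = list(sex_code = sex, pa_min_week = pa, height_m = h,
                       fitted_bv_liters = fitted_bv_liters, coefs = coefs)),
    class = "fm_estimate"
  )
}

#' @export
print.fm_estimate <- function(x, ...) {
  cat(sprintf("<fm_estimate> %.3f kg\n", x$fm_kg))
  invisible(x)
}

#' Per-cohort fat-mass estimation (data-frame interface)
#'
#' Vectorized wrapper over [fat_mass_eq1()]: takes a cohort tibble with
#' covariate columns and a calibrated-volume column, returns the cohort
#' with an `fm_kg` column appended.
#'
#' @param data Data frame with `sex_code`, `pa_min_week`, `height_m` and
#'   the column named by `bv_col`.
#' @param bv_col Name of the calibrated body-volume column.
#' @param coefs Regression coefficients, as in [fat_mass_eq1()].
#' @return `data` as a tibble with `fm_kg` appended.
#' @export
estimate_fat_mass <- function(data, bv_col = "fitted_bv_l",
                              coefs = fm_default_coefs) {
  stopifnot(all(c("sex_code", "pa_min_week", "height_m", bv_col) %in%
                  names(data)))
  est <- fat_mass_eq1(data, data[[bv_col]], coefs = coefs)
  dplyr::mutate(tibble::as_tibble(data), fm_kg = est$fm_kg)
}

#' Mean body-volume error of an estimator against a reference
#'
#' Absolute error = mean(estimates) - mean(references); percent error
#' uses the reference mean as base. Reported at full precision.
#'
#' @param estimates,references Equal-length numeric vectors (litres).
#' @return A one-row tibble: `absolute_error_l`, `percent_error`,
#'   `mean_estimate_l`, `mean_reference_l`, `n`.
#' @examples
#' report_bv_error(72.31, 67.03)  # 5.28 L, 7.88 %
#' @export
report_bv_error <- function(estimates, references) {
  if (length(estimates) != length(references) || length(estimates) < 1)
    stop_bodyscan("shape_error", "estimates and references lengths differ")
  abs_err <- mean(estimates) - mean(references)
  tibble::tibble(
    absolute_error_l = abs_err,
    percent_error = abs_err / mean(references) * 100,
    mean_estimate_l = mean(estimates),
    mean_reference_l = mean(references),
    n = length(estimates)
  )
}
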