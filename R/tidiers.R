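#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return One row per reported quantity (bias, SD, limits of agreement)
#'   with its confidence interval where defined.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean_diff", "sd_diff", "loa_low", "loa_high"),
    estimate = c(x$mean_diff, x$sd_diff, x$loa_low, x$loa_high),
    conf_low = c(x$ci_mean[1], NA, x$ci_loa_low[1], x$ci_loa_high[1]),
    conf_high = c(x$ci_mean[2], NA, x$ci_loa_low[2], x$ci_loa_high[2])
  )
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 frac_within_loa = x$frac_within_loa)
}

#' Tidy a body-volume calibration
#'
#' @param x A [fit_bv_calibration()] object.
#' @param ... Unused.
#' @export
tidy.bv_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std_error = s$coefficients[, 2])
}

#' @rdname tidy.bv_calibration
#' @export
glance.bv_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, n = x$n_fit,
                 residual_sd = x$residual_sd,
                 r_squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Tidy an ICC result
#'
#' @param x An [icc()] object.
#' @param ... Unused.
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(form = x$form, estimate = x$icc_value,
                 conf_low = x$ci[1], conf_high = x$ci[2],
                 n_subjects = x$n_subjects, k_raters = x$k_raters)
}

#' Best model summary of a best-subsets search
#'
#' @param x A [best_subsets()] tibble.
#' @param ... Unused.
#' @return The top-ranked row.
#' @export
glance.best_subsets <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x[1, ]), -"coefficients")
}
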