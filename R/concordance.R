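#' Bland-Altman agreement analysis
#'
#' Pairwise differences `a - b`: mean (bias), SD (n - 1 denominator),
#' limits of agreement at mean +/- 1.96 SD, a t-based confidence interval
#' for the bias, and the standard Bland-Altman interval for each limit
#' (SE = `SD * sqrt(1/n + 1.96^2 / (2 (n - 1)))`, t quantile with n - 1
#' degrees of freedom). Also reports the fraction of pairs inside the
#' limits.
#'
#' @param a,b Equal-length numeric vectors (n >= 3) of paired
#'   measurements by the two methods.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @param multiplier Limits-of-agreement multiplier (fixed 1.96 by
#'   convention).
#' @return An object of class `bland_altman` with fields `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `ci_mean`,
#'   `ci_loa_low`, `ci_loa_high`, `frac_within_loa`, `multiplier` and the
#'   pair tibble. Methods: [tidy()], [glance()], [autoplot()].
#' @export
bland_altman <- function(a, b, conf_level = 0.95, multiplier = 1.96) {
  if (length(a) != length(b))
    stop_bodyscan("input_error", "paired vectors must have equal length")
  n <- length(a)
  if (n < 3) stop_bodyscan("input_error", "need at least 3 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  loa <- c(m - multiplier * s, m + multiplier * s)
  tq <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
  se_mean <- s / sqrt(n)
  se_loa <- s * sqrt(1 / n + multiplier^2 / (2 * (n - 1)))
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         loa_low = loa[1], loa_high = loa[2],
         ci_mean = c(m - tq * se_mean, m + tq * se_mean),
         ci_loa_low = c(loa[1] - tq * se_loa, loa[1] + tq * se_loa),
         ci_loa_high = c(loa[2] - tq * se_loa, loa[2] + tq * se_loa),
         frac_within_loa = mean(d >= loa[1] & d <= loa[2]),
         multiplier = multiplier, conf_level = conf_level,
         pairs = tibble::tibble(a = a, b = b,
                                mean = (a + b) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n", x$n))
  cat(sprintf("  bias %.4f (%.0f%% CI %.4f to %.4f)\n", x$mean_diff,
              100 * x$conf_level, x$ci_mean[1], x$ci_mean[2]))
  cat(sprintf("  SD of differences %.4f\n", x$sd_diff))
  cat(sprintf("  LoA %.4f to %.4f (%.1f%% of pairs within)\n",
              x$loa_low, x$loa_high, 100 * x$frac_within_loa))
  invisible(x)
}

#' Limits of agreement from summary statistics
#'
#' `mean_diff +/- multiplier * sd_diff`; the arithmetic used to audit a
#' published agreement table without the subject-level pairs.
#'
#' @param mean_diff Mean of the paired differences.
#' @param sd_diff Standard deviation (n - 1) of the differences (>= 0).
#' @param multiplier Defaults to 1.96.
#' @return Named numeric vector `c(loa_low, loa_high)`.
#' @examples
#' loa_from_summary(0.1670, 3.7504)
#' @export
loa_from_summary <- function(mean_diff, sd_diff, multiplier = 1.96) {
  if (sd_diff < 0)
    stop_bodyscan("domain_error", "sd_diff must be non-negative")
  c(loa_low = mean_diff - multiplier * sd_diff,
    loa_high = mean_diff + multiplier * sd_diff)
}

#' Intraclass correlation coefficient for a ratings grid
#'
#' Two-way ANOVA decomposition of an `n x k` grid (subjects by raters)
#' into subject, rater and error mean squares. `ICC(2,1)` (two-way
#' random, absolute agreement) is
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`; `ICC(3,1)`
#' (two-way mixed, consistency) is `(MSR - MSE) / (MSR + (k-1) MSE)`.
#' Confidence intervals use the F-distribution bounds (Shrout-Fleiss /
#' McGraw-Wong), with a Satterthwaite degrees-of-freedom approximation
#' for `ICC(2,1)`.
#'
#' @param ratings Numeric matrix, `n` subjects (rows) x `k` raters
#'   (columns), no missing cells, `n >= 3`, `k >= 2`.
#' @param form `"ICC(2,1)"` (default) or `"ICC(3,1)"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `icc_result`: `icc_value`, `ci`, `form`,
#'   `n_subjects`, `k_raters` and the mean squares.
#' @export
icc <- function(ratings, form = c("ICC(2,1)", "ICC(3,1)"),
                conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings))
    stop_bodyscan("not_supported", "missing cells are not supported")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2)
    stop_bodyscan("input_error", "need at least 3 subjects and 2 raters")
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  ss_total <- sum((ratings - gm)^2)
  ss_rows <- k * sum((rm_ - gm)^2)
  ss_cols <- n * sum((cm - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (ss_total < 1e-300)
    stop_bodyscan("undefined_icc", "zero total variance: ICC undefined")
  alpha <- 1 - conf_level
  if (form == "ICC(2,1)") {
    val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * val / (n * (1 - val))
    b <- 1 + k * val * (n - 1) / (n * (1 - val))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * (a * msc + b * mse)) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - a * msc - b * mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    val <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, n - 1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  if (val <= 0)
    warn_bodyscan("degenerate_icc",
                  "non-positive ICC: no subject variance beyond error")
  structure(
    list(icc_value = val, ci = c(min(lo, val), max(hi, val)), form = form,
         n_subjects = n, k_raters = k, conf_level = conf_level,
         ms = c(msr = msr, msc = msc, mse = mse)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.4f (%.0f%% CI %.4f to %.4f), n = %d, k = %d\n",
              x$form, x$icc_value, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_subjects, x$k_raters))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample SD (n - 1) divided by the mean; dimensionless.
#'
#' @param values Numeric vector (n >= 2, nonzero mean).
#' @return The coefficient of variation.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (abs(m) < 1e-300)
    stop_bodyscan("undefined_error", "zero mean: CV undefined")
  stats::sd(values) / m
}
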