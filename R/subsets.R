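#' Exhaustive best-subsets regression
#'
#' Fits ordinary least squares for every non-empty subset of the
#' candidate predictors (all `2^p - 1` of them) and reports, per subset,
#' R-squared, adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)` and Mallows'
#' `Cp = RSS_p / MSE_full - n + 2 (p + 1)`, where `MSE_full` is the
#' residual mean square of the model with all candidates. The full model
#' satisfies `Cp = p + 1` exactly. Rank-deficient subsets are skipped
#' with a warning.
#'
#' @param data Data frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Character vector of candidate predictor columns
#'   (default: every other numeric column).
#' @param criterion Ranking criterion: `"adjusted_r2"` (default), `"r2"`
#'   (max R-squared, best model per subset size first) or `"cp"`
#'   (closest to p + 1 from below, i.e. smallest).
#' @return A tibble of class `best_subsets`, one row per subset, ordered
#'   by rank: `predictors` (comma-joined names), `p`, `r2`,
#'   `adjusted_r2`, `mallows_cp`, `coefficients` (list column of named
#'   vectors), `n`. Attribute `response` records the response name.
#' @examples
#' d <- data.frame(y = 1:10 + 0.1 * rnorm(10), x1 = 1:10, x2 = rnorm(10))
#' best_subsets(d, "y")
#' @export
best_subsets <- function(data, response,
                         predictors = setdiff(names(data), response),
                         criterion = c("adjusted_r2", "r2", "cp")) {
  criterion <- match.arg(criterion)
  stopifnot(response %in% names(data), length(predictors) >= 1,
            all(predictors %in% names(data)))
  n <- nrow(data)
  p_max <- length(predictors)
  if (n <= p_max + 1)
    stop_bodyscan("input_error",
                  "need more observations than predictors plus one")
  y <- data[[response]]
  full <- stats::lm(stats::reformulate(predictors, response), data = data)
  if (any(is.na(stats::coef(full))))
    stop_bodyscan("input_error", "full model is rank deficient")
  mse_full <- sum(stats::residuals(full)^2) / (n - p_max - 1)
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (size in seq_len(p_max)) {
    for (sel in utils::combn(predictors, size, simplify = FALSE)) {
      fit <- stats::lm(stats::reformulate(sel, response), data = data)
      if (any(is.na(stats::coef(fit)))) {
        warn_bodyscan("rank_deficient",
                      paste0("skipping rank-deficient subset: ",
                             paste(sel, collapse = "+")))
        next
      }
      rss <- sum(stats::residuals(fit)^2)
      p <- length(sel)
      r2 <- 1 - rss / tss
      rows[[length(rows) + 1]] <- tibble::tibble(
        predictors = paste(sel, collapse = ","),
        p = p,
        r2 = r2,
        adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
        mallows_cp = rss / mse_full - n + 2 * (p + 1),
        coefficients = list(stats::coef(fit)),
        n = n
      )
    }
  }
  if (length(rows) == 0)
    stop_bodyscan("input_error", "all candidate subsets were rank deficient")
  out <- dplyr::bind_rows(rows)
  out <- switch(criterion,
    adjusted_r2 = dplyr::arrange(out, dplyr::desc(.data$adjusted_r2)),
    r2 = dplyr::arrange(out, .data$p, dplyr::desc(.data$r2)) |>
      dplyr::group_by(.data$p) |>
      dplyr::mutate(.best_in_size = dplyr::row_number() == 1L) |>
      dplyr::ungroup() |>
      dplyr::arrange(dplyr::desc(.data$.best_in_size),
                     dplyr::desc(.data$adjusted_r2)) |>
      dplyr::select(-".best_in_size"),
    cp = dplyr::arrange(out, .data$mallows_cp)
  )
  attr(out, "response") <- response
  attr(out, "criterion") <- criterion
  class(out) <- c("best_subsets", class(out))
  out
}
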