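#' Fit a participant's linear input transform
#'
#' Discrete stimulus levels (1-13) and ratings (0-100) live on different
#' scales. For each participant, the inputs at perception trials are
#' regressed (ordinary least squares) onto the perception responses,
#' `response ~ slope * input + intercept`, and the fitted line maps the whole
#' input sequence onto the response scale. If any transformed value of the
#' observed inputs comes out negative, the line is refit by non-linear least
#' squares with the intercept constrained to be non-negative.
#'
#' @param data Trial tibble containing at least `input`, `response`,
#'   `response_type`; only perception trials with a response are used.
#'   Alternatively pass raw vectors via `input` and `response`.
#' @param input,response Optional numeric vectors overriding `data`.
#' @return An `input_transform` object: list with `slope`, `intercept`,
#'   `constrained` (logical: was the intercept constraint activated).
#' @examples
#' tr <- input_transform(slope = 5, intercept = 15)
#' apply_transform(tr, 7)
#' @export
fit_input_transform <- function(data = NULL, input = NULL, response = NULL) {
  if (is.null(input)) {
    stopifnot(is.data.frame(data))
    rows <- data$response_type == "perception" & !is.na(data$response)
    input <- data$input[rows]
    response <- data$response[rows]
  }
  keep <- !is.na(input) & !is.na(response)
  input <- input[keep]
  response <- response[keep]
  if (length(unique(input)) < 2) {
    abort("Need >= 2 distinct input levels among perception trials.")
  }
  fit <- lm(response ~ input)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  constrained <- FALSE
  if (any(slope * input + intercept < 0)) {
    nls_fit <- minpack.lm::nlsLM(
      response ~ intercept + slope * input,
      start = list(intercept = max(intercept, 0), slope = slope),
      lower = c(intercept = 0, slope = -Inf)
    )
    slope <- unname(coef(nls_fit)["slope"])
    intercept <- unname(coef(nls_fit)["intercept"])
    constrained <- TRUE
  }
  if (abs(slope) < sqrt(.Machine$double.eps)) {
    abort("Degenerate transform: fitted slope is zero.")
  }
  input_transform(slope, intercept, constrained)
}

#' @rdname fit_input_transform
#' @param slope,intercept Line coefficients (response units per level;
#'   response units).
#' @param constrained Was the intercept >= 0 constraint active during
#'   fitting.
#' @export
input_transform <- function(slope, intercept, constrained = FALSE) {
  check_scalar_number(slope, "slope")
  check_scalar_number(intercept, "intercept")
  structure(
    list(slope = slope, intercept = intercept,
         constrained = isTRUE(constrained)),
    class = "input_transform"
  )
}

#' @export
print.input_transform <- function(x, ...) {
  cat(sprintf("<input_transform> response = %.4g * input + %.4g%s\n",
              x$slope, x$intercept,
              if (x$constrained) " (intercept constrained >= 0)" else ""))
  invisible(x)
}

#' Apply a fitted input transform
#'
#' @param transform An [input_transform()].
#' @param x Numeric vector of intensity levels (or a trial tibble with an
#'   `input` column, returned with `input` transformed).
#' @return Transformed values on the response scale, same shape as `x`.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "input_transform"))
  if (is.data.frame(x)) {
    x$input <- transform$slope * x$input + transform$intercept
    return(x)
  }
  transform$slope * x + transform$intercept
}

rmse <- function(a, b) {
  if (length(a) == 0 || length(a) != length(b)) {
    abort("Need equal-length, non-empty vectors.")
  }
  sqrt(mean((a - b)^2))
}

#' Model-naive performance: root-mean-square error of ratings
#'
#' `rmse_perception()` scores perception ratings against the transformed
#' input on the same trial; `rmse_prediction()` scores prediction ratings at
#' trial t against the transformed input at trial t + 1 (a prediction on the
#' final trial, having no successor, is dropped before calling).
#'
#' @param response Ratings at the scored trials.
#' @param input Transformed inputs aligned with `response` (for prediction,
#'   already shifted to the next trial's input).
#' @return The RMSE (response-scale units).
#' @export
rmse_perception <- function(response, input) rmse(input, response)

#' @rdname rmse_perception
#' @export
rmse_prediction <- function(response, input) rmse(input, response)

#' Per-participant RMSE table
#'
#' Convenience wrapper computing perception and prediction RMSE per
#' participant x condition from a full trial table. Prediction responses at
#' trial t are aligned with the next trial's input within each
#' participant-condition block; the final trial's prediction (if any) is
#' dropped.
#'
#' @param data Trial tibble with `participant`, `condition`, `trial`,
#'   `input`, `response_type`, `response` (input already on the response
#'   scale).
#' @return Tibble with columns `participant`, `condition`, `response_type`,
#'   `rmse`, `n`.
#' @export
rmse_scores <- function(data) {
  data |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(next_input = dplyr::lead(.data$input)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      target = ifelse(.data$response_type == "perception",
                      .data$input, .data$next_input)
    ) |>
    dplyr::filter(!is.na(.data$response), !is.na(.data$target)) |>
    dplyr::group_by(.data$participant, .data$condition,
                    .data$response_type) |>
    dplyr::summarise(
      rmse = rmse(.data$target, .data$response),
      n = dplyr::n(),
      .groups = "drop"
    )
}
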