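#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for every printed percentage and
#' ratio in the package reports. Base R's `round()` rounds half to even;
#' published clinical tables almost always round half up, so reported
#' frequencies such as 16.65 -> 16.7 match the printed style.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(2.25, 1) # 2.3, where round() gives 2.2
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  # the 1e-9 relative nudge absorbs binary-representation error in values
  # that are exact halves in decimal (e.g. 0.125 stored as 0.12499999...)
  trunc(abs(x) * scale + 0.5 + 1e-9 * sign(abs(x))) / scale * sign(x)
}

#' Percentage of a count over a denominator
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive and `numerator <= denominator`.
#' @param decimals Decimal places for half-up rounding (default 1).
#' @return `100 * numerator / denominator`, rounded half-up.
#' @examples
#' frequency(23, 863)      # 2.7
#' frequency(8, 863, 2)    # 0.93
#' @export
frequency <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "sfscreenr_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator].", class = "sfscreenr_error")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

# internal: stop with a validation error listing offending items
validation_error <- function(msg, items = NULL) {
  if (!is.null(items) && length(items)) {
    items <- utils::head(items, 10)
    msg <- paste0(msg, "\n  offending: ", paste(items, collapse = "; "))
  }
  abort(msg, class = c("sfscreenr_validation_error", "sfscreenr_error"))
}

# internal: semicolon-joined string -> list of character vectors
split_semi <- function(x) {
  out <- stringr::str_split(dplyr::coalesce(x, ""), ";")
  lapply(out, function(v) v[nzchar(v)])
}

join_semi <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}
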