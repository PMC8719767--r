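#' Standardize a numeric predictor and shift it by two
#'
#' Centers and scales a numeric vector to unit sample standard deviation
#' (n - 1 denominator) and then adds 2, so standardized predictors stay
#' positive.  The centering and scaling constants are kept as attributes for
#' back-transformation of estimates to original units.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return The transformed vector, with attributes `center` and `scale`.
#' @examples
#' scale_plus_two(c(2, 4, 6)) # 1 2 3
#' @export
scale_plus_two <- function(x) {
  if (!is.numeric(x) || length(x) < 2)
    abort("`x` must be a numeric vector of length >= 2",
          class = "morphburden_scale_error")
  if (anyNA(x)) abort("`x` contains missing values",
                      class = "morphburden_scale_error")
  ctr <- mean(x)
  scl <- sd(x)
  if (!is.finite(scl) || scl == 0)
    abort("`x` is constant; cannot standardize a zero-variance predictor",
          class = "morphburden_scale_error")
  out <- (x - ctr) / scl + 2
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Invert the scale-then-add-2 transform
#'
#' @param z Transformed values (or a coefficient on the transformed scale if
#'   `slope = TRUE`).
#' @param center,scale Constants from [scale_plus_two()].
#' @param slope If `TRUE`, treat `z` as a regression slope and divide by
#'   `scale` instead of inverting the location shift.
#' @return Numeric vector on the original scale.
#' @export
unscale_plus_two <- function(z, center, scale, slope = FALSE) {
  if (slope) return(z / scale)
  (z - 2) * scale + center
}
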