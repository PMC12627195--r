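# Circular angle arithmetic on the 360-degree color wheel.
# All angles are in degrees. Signed offsets live in (-180, 180]; exactly
# opposite hues map to +180 by convention so that binning is deterministic.

#' Wrap an angle difference to a signed offset in (-180, 180]
#'
#' @param raw Numeric vector of angles or angle differences in degrees
#'   (any finite real value).
#' @return Numeric vector congruent to `raw` modulo 360, in `(-180, 180]`.
#' @examples
#' wrap_signed(c(20, -340, 539, -180))
#' @export
wrap_signed <- function(raw) {
  if (!is.numeric(raw) || any(!is.finite(raw)))
    stop("'raw' must be finite numeric")
  out <- raw %% 360
  out[out > 180] <- out[out > 180] - 360
  # x %% 360 is in [0, 360) so -180 never occurs here, but guard against
  # floating representations of exact multiples
  out[out <= -180] <- out[out <= -180] + 360
  out
}

#' Normalize an angle to the color wheel [0, 360)
#'
#' @param angle Numeric vector in degrees.
#' @return Values in `[0, 360)`.
#' @export
wrap_angle <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle)))
    stop("'angle' must be finite numeric")
  angle %% 360
}

#' Signed angular difference a - b
#'
#' Positive results mean `a` lies clockwise of `b` on the wheel.
#'
#' @param a,b Angles in degrees.
#' @return Signed offsets in `(-180, 180]`.
#' @examples
#' signed_difference(10, 350)  # +20, crosses the 0/360 seam
#' @export
signed_difference <- function(a, b) {
  wrap_signed(wrap_angle(a) - wrap_angle(b))
}

#' Circular mean of signed offsets
#'
#' Direction of the mean resultant vector, wrapped to `(-180, 180]`. For a
#' pair of angles, or any sample symmetric about its center, this equals
#' the arithmetic mean; for concentrated samples it is close to it. A
#' (near-)zero resultant length has no defined direction and is an error
#' rather than a silent arbitrary value.
#'
#' @param offsets Non-empty numeric vector of angles in degrees.
#' @param tol Resultant length below which the mean is declared undefined.
#' @return Scalar circular mean in `(-180, 180]`.
#' @examples
#' circular_mean(c(170, -170))  # 180, not 0
#' @export
circular_mean <- function(offsets, tol = 1e-8) {
  if (length(offsets) == 0L) stop("'offsets' must be non-empty")
  if (!is.numeric(offsets) || any(!is.finite(offsets)))
    stop("'offsets' must be finite numeric")
  rad <- offsets * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < tol)
    stop("circular mean undefined: mean resultant length is zero")
  wrap_signed(atan2(s, c) * 180 / pi)
}
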