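# The first-derivative-of-Gaussian (DoG) bias curve:
#   y(x) = alpha * w * x * c * exp(-(w x)^2) + beta,  c = sqrt(2) / exp(-1/2)
# The normalization constant c makes the curve's peak height equal alpha
# exactly, so alpha is read directly as the peak bias in degrees.

#' Normalization constant of the DoG bias curve
#'
#' `sqrt(2)/exp(-0.5)`, chosen so that the extremum of
#' `alpha * w * x * c * exp(-(w x)^2)` equals `alpha`.
#'
#' @return A scalar, approximately 2.3316.
#' @export
dog_constant <- function() sqrt(2) / exp(-0.5)

#' Evaluate the DoG serial-bias curve
#'
#' @param x Relative feature value(s) of the previous trial, degrees,
#'   typically in `(-180, 180]`.
#' @param alpha Signed peak amplitude in degrees; positive = attraction.
#' @param w Width scale in 1/degrees, must be positive.
#' @param beta Intercept in degrees (overall bias independent of `x`).
#' @return Predicted bias in degrees, same length as `x`.
#' @examples
#' dog(45, alpha = 1, w = 1/45)        # c * exp(-1)
#' dog(dog_peak_location(0.02), alpha = 6.16, w = 0.02)  # the peak: 6.16
#' @export
dog <- function(x, alpha, w, beta = 0) {
  if (any(w <= 0)) stop("'w' must be positive")
  alpha * w * x * dog_constant() * exp(-(w * x)^2) + beta
}

#' Location of the DoG peak
#'
#' The positive `x` maximizing `|dog(x) - beta|`, in closed form
#' `1 / (w * sqrt(2))`; the curve there equals `beta + alpha`.
#'
#' @param w Width scale in 1/degrees, positive.
#' @return Peak location in degrees.
#' @export
dog_peak_location <- function(w) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("'w' must be positive and finite")
  1 / (w * sqrt(2))
}
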