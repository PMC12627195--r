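# Deterministic least-squares DoG fit. For a fixed width w the model is
# linear in (alpha, beta), so the fit profiles w: a coarse grid over w with
# closed-form (alpha, beta) at each node, followed by golden-section
# refinement of the profiled sum of squares. No randomness is involved, which
# makes this the reference fit against which the Bayesian machinery is tested.

profile_sse <- function(w, x, y) {
  g <- w * x * dog_constant() * exp(-(w * x)^2)
  fit <- lm.fit(cbind(g = g, intercept = 1), y)
  list(sse = sum(fit$residuals^2),
       alpha = unname(fit$coefficients["g"]),
       beta = unname(fit$coefficients["intercept"]))
}

#' Least-squares fit of the DoG bias curve
#'
#' Minimizes the sum of squared residuals of [dog()] over `(alpha, w, beta)`.
#' Width is profiled on a log-spaced grid within `w_bounds` and refined with
#' [stats::optimize()]; amplitude and intercept are solved in closed form at
#' each width. Deterministic given the inputs.
#'
#' @param x Relative feature values in degrees (not all equal, and not all
#'   zero).
#' @param y Observed mean biases in degrees, same length as `x`.
#' @param w_bounds Length-2 interval of admissible widths (1/degrees),
#'   both positive.
#' @param n_grid Number of coarse grid nodes for the width profile.
#' @return An object of class `"dog_ls"`: a list with `coefficients`
#'   (named vector `alpha`, `w`, `beta`), `sse`, `fitted.values`,
#'   `residuals`, and the data.
#' @examples
#' x <- c(seq(-144, 144, by = 36), 180)
#' y <- dog(x, alpha = 2, w = 0.02)
#' coef(fit_dog_ls(x, y))
#' @export
fit_dog_ls <- function(x, y, w_bounds = c(0.003, 0.2), n_grid = 60L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 4L) stop("need at least 4 (x, y) pairs")
  if (all(x == x[1])) stop("degenerate design: all x equal")
  if (all(x == 0)) stop("degenerate design: all x zero")
  if (length(w_bounds) != 2L || any(w_bounds <= 0) || diff(w_bounds) <= 0)
    stop("'w_bounds' must be an increasing positive interval")

  grid <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = n_grid))
  sses <- vapply(grid, function(w) profile_sse(w, x, y)$sse, numeric(1))
  k <- which.min(sses)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(n_grid, k + 1L)]
  opt <- optimize(function(w) profile_sse(w, x, y)$sse, c(lo, hi),
                  tol = 1e-10)
  w_hat <- opt$minimum
  prof <- profile_sse(w_hat, x, y)

  structure(
    list(coefficients = c(alpha = prof$alpha, w = w_hat, beta = prof$beta),
         sse = prof$sse,
         fitted.values = dog(x, prof$alpha, w_hat, prof$beta),
         residuals = y - dog(x, prof$alpha, w_hat, prof$beta),
         data = list(x = x, y = y),
         w_bounds = w_bounds),
    class = "dog_ls")
}

#' @export
print.dog_ls <- function(x, digits = 4, ...) {
  cat("Least-squares DoG fit\n")
  print(round(x$coefficients, digits))
  cat("SSE:", format(x$sse, digits = digits), "on", length(x$data$x),
      "condition means\n")
  invisible(x)
}

#' @export
coef.dog_ls <- function(object, ...) object$coefficients

#' @export
predict.dog_ls <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  cf <- object$coefficients
  dog(x, cf["alpha"], cf["w"], cf["beta"])
}

#' @export
residuals.dog_ls <- function(object, ...) object$residuals

#' @export
fitted.dog_ls <- function(object, ...) object$fitted.values
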