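#' Burg autoregressive coefficients of a single window
#'
#' Fits an autoregressive model of order `P` by Burg's method, which chooses
#' each reflection coefficient to minimise the summed forward and backward
#' prediction error while the coefficients satisfy the Levinson-Durbin
#' recursion; the resulting model is always stable (all reflection
#' coefficients inside the unit interval).
#'
#' Coefficients are returned in the convention
#' `x(t) = -sum_i a_i x(t - i) + e(t)`, i.e. the negated prediction weights.
#' A long realisation of `x(t) = 0.9 x(t-1) + e(t)` therefore yields
#' `a_1` close to `-0.9`.  The window is demeaned before fitting, and the
#' coefficients are invariant under scaling of the input.
#'
#' @param x Numeric vector of samples, non-constant, with `length(x) > 2 * order`.
#' @param order Model order `P` (number of coefficients), default 10 — a
#'   common choice for short EEG windows.
#' @return An object of class `ar_model`: a list with `order`, `coefficients`
#'   (length `P`, sign convention above), `reflection` (partial
#'   autocorrelations, all in (-1, 1)), and `noise_variance` (residual power).
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::arima.sim(list(ar = 0.9), 10000))
#' burg_ar(x, order = 1)$coefficients   # close to -0.9
#' @export
burg_ar <- function(x, order = 10) {
  x <- as.numeric(x)
  N <- length(x)
  if (!(is.numeric(order) && length(order) == 1 && order == round(order) && order >= 1)) {
    stop("burg_ar(): order must be a positive integer")
  }
  order <- as.integer(order)
  if (order >= N / 2) {
    stop("burg_ar(): order P = ", order, " must be < N/2 (N = ", N, ")")
  }
  if (!all(is.finite(x))) stop("burg_ar(): samples must be finite")
  if (stats::sd(x) == 0) {
    stop("burg_ar(): constant input has no autoregressive structure")
  }

  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  structure(
    list(order = order,
         coefficients = -as.numeric(fit$ar),
         reflection = as.numeric(fit$partialacf),
         noise_variance = as.numeric(fit$var.pred)),
    class = "ar_model"
  )
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("Burg AR(%d) model, residual variance %.4g\n",
              x$order, x$noise_variance))
  print(round(x$coefficients, 4))
  invisible(x)
}
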