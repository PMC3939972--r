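#' Higuchi fractal dimension of a single window
#'
#' Estimates the fractal dimension of a signal viewed as a planar curve from
#' the scaling of its average curve length with the sampling delay.  For each
#' delay `k = 1..k_max` and each offset `m = 1..k` the decimated series
#' `x(m), x(m + k), x(m + 2k), ...` has curve length
#' `L_m(k) = (1/k) * sum |x(m + i k) - x(m + (i-1) k)| * (N - 1) / (floor((N - m)/k) * k)`,
#' and the delay's length `L(k)` averages `L_m(k)` over the `k` offsets.
#' `L(k)` is proportional to `k^-D`; the fractal dimension `D` is the slope of
#' the least-squares fit of `ln L(k)` against `ln(1/k)` with equal weights.
#' A straight line gives `D = 1`; white noise approaches `D = 2`.
#'
#' @param x Numeric vector of samples, non-constant, with `length(x) > 2 * k_max`.
#' @param k_max Maximum delay, default 8 (keeps at least ~49 points per
#'   decimated series for a 400-sample window).  Must be at least 2: the
#'   log-log regression needs two points.
#' @return An object of class `higuchi_fd`: a list with the delays `k`, the
#'   average lengths `lengths` (`L(k)`), and the fractal dimension `D`.
#' @examples
#' higuchi_fd(seq_len(400))$D       # smooth line: D ~ 1
#' set.seed(1); higuchi_fd(rnorm(400))$D   # white noise: D ~ 2
#' @export
higuchi_fd <- function(x, k_max = 8) {
  x <- as.numeric(x)
  N <- length(x)
  if (!(is.numeric(k_max) && length(k_max) == 1 && k_max == round(k_max) && k_max >= 2)) {
    stop("higuchi_fd(): k_max must be an integer >= 2 (the regression needs two points)")
  }
  k_max <- as.integer(k_max)
  if (N <= 2L * k_max) {
    stop("higuchi_fd(): need length(x) > 2 * k_max (got N = ", N,
         ", k_max = ", k_max, ")")
  }
  if (!all(is.finite(x))) stop("higuchi_fd(): samples must be finite")
  if (max(x) == min(x)) {
    stop("higuchi_fd(): constant input has no defined fractal dimension")
  }

  L <- numeric(k_max)
  for (k in seq_len(k_max)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      n_i <- (N - m) %/% k
      idx <- m + (0:n_i) * k
      Lm[m] <- sum(abs(diff(x[idx]))) * (N - 1) / (n_i * k) / k
    }
    L[k] <- mean(Lm)
  }
  if (any(L <= 0)) {
    stop("higuchi_fd(): zero curve length at some delay; input is locally constant")
  }
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(k_max))), log(L))
  structure(
    list(k = seq_len(k_max), lengths = L, D = unname(fit$coefficients[2])),
    class = "higuchi_fd"
  )
}

#' @export
print.higuchi_fd <- function(x, ...) {
  cat(sprintf("Higuchi fractal dimension: D = %.3f (k_max = %d)\n",
              x$D, max(x$k)))
  invisible(x)
}
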