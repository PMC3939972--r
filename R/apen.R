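#' Approximate entropy of a single window
#'
#' Approximate entropy (ApEn) quantifies the regularity of a time series: it is
#' the negative average log conditional probability that runs of `m` samples
#' that are close (within tolerance `r`, Chebyshev norm) remain close when the
#' run is extended to `m + 1` samples.  Larger values indicate a more irregular
#' signal.  Healthy resting EEG is typically more irregular (higher ApEn) than
#' pathologically regular activity, which is what makes the statistic a
#' discriminative EEG feature.
#'
#' The tolerance defaults to `r_coefficient` times the standard deviation of
#' the window being analysed (population formula, divide by `N`), which makes
#' ApEn exactly invariant under scaling and translation of the signal.  Pass
#' `r_absolute` to use a fixed tolerance instead (for example one derived from
#' a whole recording).
#'
#' Two self-match conventions are supported.  `"exclude"` skips the comparison
#' of a template with itself while keeping the denominator `N - q + 1`
#' unchanged; `"include"` counts it (the classical convention, which
#' guarantees every match frequency is positive).  Under `"exclude"` a
#' template with zero matches makes the logarithm undefined and raises an
#' error naming the offending template; this does not occur for EEG-scale
#' windows at the default tolerance.
#'
#' @param x Numeric vector of samples; at least 50 points are required for the
#'   statistic to be meaningful.
#' @param m Embedding run length (template length), default 2.
#' @param r_coefficient Tolerance as a multiple of the window SD, default 0.1.
#' @param r_absolute Optional absolute tolerance overriding `r_coefficient`.
#' @param self_match `"exclude"` (default) or `"include"`.
#' @return An object of class `apen_computation`: a list with the sample count
#'   `N`, embedding `m`, absolute tolerance `r`, the per-template match counts
#'   `count_m` / `count_m1`, match frequencies `C_m` / `C_m1`, the mean log
#'   frequencies `phi_m` / `phi_m1`, and `value = phi_m - phi_m1`.
#' @examples
#' set.seed(1)
#' # white noise is irregular: high ApEn (classical self-match convention)
#' apen(rnorm(400), self_match = "include")$value
#' # a near-pure tone is regular: low ApEn
#' apen(sin(2 * pi * 10 * (0:399) / 200) + rnorm(400, sd = 0.01),
#'      self_match = "include")$value
#' @export
apen <- function(x, m = 2, r_coefficient = 0.1, r_absolute = NULL,
                 self_match = c("exclude", "include")) {
  self_match <- match.arg(self_match)
  x <- as.numeric(x)
  N <- length(x)
  if (!all(is.finite(x))) {
    stop("apen(): samples must be finite")
  }
  if (!(is.numeric(m) && length(m) == 1 && m >= 1 && m == round(m))) {
    stop("apen(): m must be a positive integer")
  }
  m <- as.integer(m)
  if (N < 2L * m + 2L) {
    stop("apen(): window too short for embedding dimension m = ", m)
  }
  if (N < 50) {
    warning("apen(): N = ", N,
            " is below the 50-point applicability floor; ",
            "the estimate may be unreliable")
  }
  if (is.null(r_absolute)) {
    if (!(r_coefficient > 0)) stop("apen(): r_coefficient must be > 0")
    s <- sd_pop(x)
    if (s == 0) {
      stop("apen(): window has zero standard deviation; ",
           "supply r_absolute for constant signals")
    }
    r <- r_coefficient * s
  } else {
    if (!(is.numeric(r_absolute) && r_absolute > 0)) {
      stop("apen(): r_absolute must be a positive number")
    }
    r <- r_absolute
  }

  counts <- .apen_counts(x, m, r, self_match == "exclude")
  n_m <- N - m + 1L
  n_m1 <- N - m
  if (self_match == "exclude") {
    zero <- which(counts$count_m == 0L | c(counts$count_m1, 1L) == 0L)
    if (length(zero)) {
      stop("apen(): template ", zero[1],
           " has no match within tolerance r = ", signif(r, 6),
           " under the exclude convention; log(0) is undefined")
    }
  }
  C_m <- counts$count_m / n_m
  C_m1 <- counts$count_m1 / n_m1
  phi_m <- mean(log(C_m))
  phi_m1 <- mean(log(C_m1))

  structure(
    list(N = N, m = m, r = r, self_match = self_match,
         count_m = counts$count_m, count_m1 = counts$count_m1,
         C_m = C_m, C_m1 = C_m1,
         phi_m = phi_m, phi_m1 = phi_m1,
         value = phi_m - phi_m1),
    class = "apen_computation"
  )
}

#' @export
print.apen_computation <- function(x, ...) {
  cat(sprintf("Approximate entropy: %.4f (m = %d, r = %.4g, N = %d, self-match %s)\n",
              x$value, x$m, x$r, x$N, x$self_match))
  invisible(x)
}

# population SD (divide by N); the convention used for the ApEn tolerance
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# lean ApEn used in bulk window loops; numerically identical to apen()$value
.apen_fast <- function(x, m = 2, r_coefficient = 0.1,
                       self_match = "include", r_absolute = NULL) {
  r <- if (is.null(r_absolute)) {
    s <- sd_pop(x)
    if (s == 0) stop("apen: window has zero standard deviation")
    r_coefficient * s
  } else r_absolute
  v <- .apen_value(as.numeric(x), as.integer(m), r, self_match == "exclude")
  if (is.na(v)) {
    stop("apen: a template has no match within tolerance r = ", signif(r, 6),
         " under the exclude convention")
  }
  v
}
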