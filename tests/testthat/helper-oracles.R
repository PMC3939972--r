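# Independent brute-force oracles, written as direct transcriptions of the
# defining formulas with explicit loops.  They are deliberately naive and are
# never used by the package itself.

# Approximate entropy by full template-pair enumeration.
# Returns NA if some template has zero matches (log(0) undefined).
apen_bruteforce <- function(x, m, r, self_match = "exclude") {
  N <- length(x)
  phi <- function(q) {
    n <- N - q + 1
    C <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0
      for (j in seq_len(n)) {
        if (self_match == "exclude" && j == i) next
        d <- max(abs(x[i:(i + q - 1)] - x[j:(j + q - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      if (cnt == 0) return(NA_real_)
      C[i] <- cnt / n
    }
    mean(log(C))
  }
  p1 <- phi(m)
  if (is.na(p1)) return(NA_real_)
  p2 <- phi(m + 1)
  if (is.na(p2)) return(NA_real_)
  p1 - p2
}

# Higuchi fractal dimension as a naive three-loop transcription: curve
# lengths per delay k and offset m, averaged over offsets, slope of
# ln L(k) on ln(1/k).
higuchi_naive <- function(x, k_max) {
  N <- length(x)
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    s <- 0
    for (m in seq_len(k)) {
      n_i <- floor((N - m) / k)
      L <- 0
      for (i in seq_len(n_i)) {
        L <- L + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      s <- s + L * (N - 1) / (n_i * k) / k
    }
    Lk[k] <- s / k
  }
  ks <- seq_len(k_max)
  fit <- stats::lm(log(Lk) ~ log(1 / ks))
  list(lengths = Lk, D = unname(stats::coef(fit)[2]))
}

# Burg recursion transcribed directly: at each stage the reflection
# coefficient minimises the summed forward + backward prediction error and
# the coefficients are updated by Levinson-Durbin.  Returns coefficients in
# the x(t) = -sum a_i x(t - i) convention.
burg_naive <- function(x, P) {
  x <- x - mean(x)
  N <- length(x)
  f <- x
  b <- x
  a <- numeric(0)
  for (p in seq_len(P)) {
    ff <- f[(p + 1):N]
    bb <- b[p:(N - 1)]
    k <- -2 * sum(ff * bb) / (sum(ff^2) + sum(bb^2))
    a <- c(a + k * rev(a), k)
    f_new <- f
    b_new <- b
    for (n in (p + 1):N) {
      f_new[n] <- f[n] + k * b[n - 1]
      b_new[n] <- b[n - 1] + k * f[n]
    }
    f <- f_new
    b <- b_new
  }
  a
}

# Paired t statistic and two-sided p value from the textbook formulas.
paired_t_naive <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df = n - 1))
}

# Decision function of a trained kernel classifier evaluated as a literal
# kernel sum over all stored support vectors.
decision_bruteforce <- function(model, x) {
  xs <- (as.numeric(x) - model$center) / model$scale
  f <- 0
  for (i in seq_len(nrow(model$sv))) {
    f <- f + model$coefs[i] *
      exp(-sum((model$sv[i, ] - xs)^2) / (2 * model$sigma^2))
  }
  f - model$b
}
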