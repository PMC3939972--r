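test_that("constant sequence with self-match included has ApEn exactly 0", {
  x <- rep(3.7, 100)
  res <- apen(x, r_absolute = 0.5, self_match = "include")
  expect_identical(res$value, 0)
  expect_identical(res$phi_m, 0)
  expect_identical(res$phi_m1, 0)
  expect_true(all(res$C_m == 1))
})

test_that("periodic sequence matches the frozen brute-force oracle value", {
  x <- c(2, 4, 6, 2, 4, 6, 2, 4, 6, 2)
  expect_warning(res <- apen(x, m = 2, r_absolute = 1, self_match = "exclude"),
                 "applicability floor")
  expect_equal(res$value, 0.055503759483603, tolerance = 1e-12)
  # and the oracle itself reproduces it on the fly
  expect_equal(res$value, apen_bruteforce(x, 2, 1, "exclude"), tolerance = 1e-14)
})

test_that("optimized ApEn equals brute-force enumeration on random sequences", {
  # smooth (random-walk) sequences keep every template matched so that both
  # self-match conventions are defined
  set.seed(42)
  for (i in 1:25) {
    n <- sample(50:200, 1)
    x <- cumsum(rnorm(n))
    r <- runif(1, 0.3, 0.8) * sd(x)
    for (conv in c("exclude", "include")) {
      o <- apen_bruteforce(x, 2, r, conv)
      if (is.na(o)) {
        expect_error(apen(x, r_absolute = r, self_match = conv), "no match")
      } else {
        expect_equal(apen(x, r_absolute = r, self_match = conv)$value, o,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("lean bulk path agrees with the full computation", {
  set.seed(7)
  for (i in 1:10) {
    x <- cumsum(rnorm(150))
    expect_equal(eegapen:::.apen_fast(x, 2, 0.4, "include"),
                 apen(x, r_coefficient = 0.4, self_match = "include")$value,
                 tolerance = 1e-12)
  }
})

test_that("ApEn is exactly scale- and translation-invariant when r tracks SD", {
  set.seed(11)
  x <- cumsum(rnorm(200))
  base <- apen(x, self_match = "include")$value
  for (c in c(2, 3.7, 10, 0.5)) {
    expect_equal(apen(c * x, self_match = "include")$value, base, tolerance = 0)
  }
  expect_equal(apen(x + 100, self_match = "include")$value, base, tolerance = 1e-12)
})

test_that("a 10 Hz tone is far more regular than white noise at N = 400", {
  fs <- 200
  t <- (0:399) / fs
  gaps <- vapply(1:20, function(seed) {
    set.seed(seed)
    tone <- apen(sin(2 * pi * 10 * t) + rnorm(400, sd = 0.01),
                 self_match = "include")$value
    noise <- apen(rnorm(400), self_match = "include")$value
    noise - tone
  }, numeric(1))
  expect_true(all(gaps > 0.3))
})

test_that("include and exclude conventions differ by O(1/N) at N = 400", {
  set.seed(13)
  for (i in 1:5) {
    x <- cumsum(rnorm(400))
    r <- 0.5 * sd(x)
    d <- abs(apen(x, r_absolute = r, self_match = "include")$value -
               apen(x, r_absolute = r, self_match = "exclude")$value)
    expect_lt(d, 0.05)
  }
})

test_that("degenerate and misconfigured inputs raise descriptive errors", {
  expect_error(apen(rep(1, 100)), "zero standard deviation")
  expect_error(apen(c(rnorm(99), NA)), "finite")
  # white noise at a tiny tolerance: some template has no neighbour
  set.seed(3)
  expect_error(apen(rnorm(400), r_coefficient = 0.01, self_match = "exclude"),
               "template")
  expect_error(apen(rnorm(100), m = 0), "positive integer")
})

test_that("the computation trace is internally consistent", {
  set.seed(5)
  x <- cumsum(rnorm(120))
  res <- apen(x, r_absolute = 0.6 * sd(x), self_match = "include")
  expect_identical(res$value, res$phi_m - res$phi_m1)
  expect_length(res$C_m, res$N - res$m + 1)
  expect_length(res$C_m1, res$N - res$m)
  expect_true(all(res$C_m > 0 & res$C_m <= 1))
})
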