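# One-off sweep fixing the oscillation-weight -> windowed-ApEn calibration
# table stored in R/synthetic.R (.apen_calib).
#
# For each broadband colour and each oscillation weight w on a grid, generate
# a few 120 s channels of the mixture x = (1 - w) * broadband + w * drifting
# alpha oscillation at 200 Hz, cut them into 2 s windows with 50% overlap,
# and record the mean windowed ApEn (m = 2, r = 0.1 * window SD, self-match
# included).  The printed table is pasted into .apen_calib; it is measured
# once and never revisited at run time.
#
# Run from the repository root:  Rscript tools/calibrate-generator.R

pkg <- "eegapen"
if (!requireNamespace(pkg, quietly = TRUE)) {
  # fall back to sourcing the tree during development
  Rcpp::sourceCpp("src/apen.cpp")
  for (f in list.files("R", full.names = TRUE)) source(f)
  apen_fun <- apen
  bb <- .broadband_noise
  osc <- .drifting_oscillation
} else {
  apen_fun <- getFromNamespace("apen", pkg)
  bb <- getFromNamespace(".broadband_noise", pkg)
  osc <- getFromNamespace(".drifting_oscillation", pkg)
}

fs <- 200; n <- 24000; N <- 400; step <- 200
wapen <- function(x) {
  starts <- seq(1, length(x) - N + 1, by = step)
  mean(vapply(starts, function(s) apen_fun(x[s:(s + N - 1)],
                                           self_match = "include")$value,
              numeric(1)))
}

grid <- c(0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.75, 0.80, 0.85, 0.90, 0.93, 0.95, 0.97)
for (colour in c("pink", "white")) {
  beta <- if (colour == "pink") 1 else 0
  cat("## ", colour, " broadband\n", sep = "")
  vals <- sapply(grid, function(w) {
    set.seed(20260923)
    mean(sapply(1:4, function(i) {
      x <- (1 - w) * bb(n, fs, beta = beta) + w * osc(n, fs, runif(1, 8.5, 11.5))
      wapen((x - mean(x)) / sd(x))
    }))
  })
  cat("w    = c(", paste(sprintf("%.2f", grid), collapse = ", "), ")\n", sep = "")
  cat("apen = c(", paste(sprintf("%.4f", vals), collapse = ", "), ")\n", sep = "")
}
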