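# brute-force oracle: dense least-squares polynomial refit in each window
sg_oracle <- function(y, window, order) {
  h <- (window - 1) / 2
  n <- length(y)
  out <- y
  for (i in (h + 1):(n - h)) {
    idx <- (i - h):(i + h)
    fit <- stats::lm.fit(outer(idx - i, 0:order, `^`), y[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

test_that("Savitzky-Golay equals a windowed least-squares refit", {
  cfg <- preprocess_config()
  const <- rep(3.7, 40)
  expect_equal(savitzky_golay(const, cfg), const)

  x <- seq_len(60)
  cubic <- 2 - 0.5 * x + 0.01 * x^2 + 0.0005 * x^3
  sm <- savitzky_golay(cubic, cfg)
  expect_equal(sm[3:58], cubic[3:58], tolerance = 1e-10)

  set.seed(42)
  y <- stats::rnorm(80)
  expect_equal(savitzky_golay(y, cfg)[3:78], sg_oracle(y, 5, 3)[3:78],
               tolerance = 1e-10)

  expect_error(savitzky_golay(stats::rnorm(3), cfg), "shorter")
})

test_that("Savitzky-Golay is linear and length-preserving", {
  cfg <- preprocess_config()
  set.seed(1)
  x <- stats::rnorm(50); z <- stats::rnorm(50)
  lhs <- savitzky_golay(2 * x + 3 * z, cfg)
  rhs <- 2 * savitzky_golay(x, cfg) + 3 * savitzky_golay(z, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_length(savitzky_golay(x, cfg), 50)
})

test_that("airPLS leaves smooth curves and recovers planted baselines", {
  cfg <- preprocess_config()
  zero <- numeric(300)
  res <- airpls_baseline(zero, cfg)
  expect_equal(res$baseline, zero)
  expect_equal(res$corrected, zero)

  # quadratic lies in the null space of the 3rd-order difference penalty
  x <- seq(0, 1, length.out = 400)
  smooth <- 5 + 2 * x - 3 * x^2
  res <- airpls_baseline(smooth, cfg)
  expect_lt(max(abs(res$corrected)), 1e-6 * max(abs(smooth)))

  # planted Gaussian peaks on a linear baseline
  base <- 1 + 2 * x
  peaks <- 4 * exp(-(x - 0.3)^2 / 0.001) + 3 * exp(-(x - 0.7)^2 / 0.002)
  res <- airpls_baseline(base + peaks, cfg)
  rmse <- sqrt(mean((res$baseline - base)^2))
  expect_lt(rmse, 0.02 * 4)

  expect_error(airpls_baseline(c(1, NA, 3), cfg), "non-finite")
})

test_that("airPLS is scale-equivariant and stays below peak apexes", {
  cfg <- preprocess_config()
  x <- seq(0, 1, length.out = 350)
  y <- 0.5 + x + 3 * exp(-(x - 0.5)^2 / 0.002) +
    sin(7 * x) * 0.05
  a <- 13.7
  expect_equal(airpls_baseline(a * y, cfg)$baseline,
               a * airpls_baseline(y, cfg)$baseline, tolerance = 1e-9)
  res <- airpls_baseline(y, cfg)
  apex <- which.max(y)
  expect_lte(res$baseline[apex], y[apex] + 1e-8)
})

test_that("sparse penalized solve matches a dense solve", {
  # contract check at converged weights: one weighted penalized solve
  n <- 200
  set.seed(9)
  y <- stats::rnorm(n) + seq_len(n) / 50
  w <- stats::runif(n)
  lambda <- 1e7
  d <- 3
  dcoef <- choose(d, 0:d) * (-1)^(0:d)
  Ddense <- matrix(0, n - d, n)
  for (j in 0:d) Ddense[cbind(seq_len(n - d), seq_len(n - d) + j)] <- dcoef[j + 1]
  z_dense <- solve(diag(w) + lambda * crossprod(Ddense), w * y)
  Dsp <- Matrix::bandSparse(n - d, n, k = 0:d,
                            diagonals = lapply(dcoef, rep, n - d))
  z_sparse <- as.numeric(Matrix::solve(lambda * Matrix::crossprod(Dsp) +
                                         Matrix::Diagonal(n, w), w * y))
  expect_equal(z_sparse, z_dense, tolerance = 1e-8)
})

test_that("SERSome preprocessing corrects peaks in place and is idempotent", {
  g <- test_grid()
  cfg <- preprocess_config()

  zeros <- manual_sersome(matrix(0, g$points, 3), g)
  expect_equal(preprocess_sersome(zeros, cfg)$intensities,
               zeros$intensities, ignore_attr = TRUE)

  # polynomial baseline-only spectra: processing twice changes nothing
  u <- (g$axis - g$start) / (g$stop - g$start)
  bl <- 2 + 0.5 * u - 0.8 * u^2
  s <- manual_sersome(cbind(bl, 1.3 * bl), g)
  once <- preprocess_sersome(s, cfg)
  twice <- preprocess_sersome(once, cfg)
  expect_equal(twice$intensities, once$intensities, tolerance = 1e-6,
               ignore_attr = TRUE)

  # planted peaks + baseline: corrected mean spectrum peaks at planted shifts
  lib <- build_reference_library()
  prof <- cell_profile("c9", "g",
                       c(spermine = 2, adenine = 1.5),
                       fluctuation_sigma = 0.2)
  raw <- simulate_sersome(prof, lib, g, n_spectra = 8, seed = 21)
  cor <- preprocess_sersome(raw, cfg)
  expect_identical(cor$cell_id, "c9")
  m <- rowMeans(cor$intensities)
  top1 <- g$axis[which.max(m)]
  expect_lte(abs(top1 - 1571), g$step)  # spermine main band
  in728 <- abs(g$axis - 728) <= 12
  expect_gt(max(m[in728]), 0.5)        # adenine band survives correction

  expect_error(sersome(matrix(Inf, g$points, 2), g), "non-finite")
})
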