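test_that("packaged reference library has the expected structure", {
  lib <- build_reference_library()
  expect_s3_class(lib, "reference_library")
  expect_length(lib$records, 20)
  carriers <- vapply(lib$records,
                     function(r) any(abs(r$peaks$shift - 1571) <= 5),
                     logical(1))
  expect_equal(sum(carriers), 12)
  expect_true(1571 %in% lib$records[["spermine"]]$peaks$shift)
  # amplitudes normalized to max 1 in every record
  for (r in lib$records) expect_equal(max(r$peaks$amp), 1)
})

test_that("library loader rejects degenerate tables", {
  empty <- tempfile(fileext = ".csv")
  writeLines("name,abbreviation,formula,peaks", empty)
  expect_error(build_reference_library(empty), "no records")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("name,abbreviation,formula,peaks",
               "x,X,C2H5NO2,1000:1.0:8",
               "x,X,C2H5NO2,1100:1.0:8"), dup)
  expect_error(build_reference_library(dup), "duplicate")

  badform <- tempfile(fileext = ".csv")
  writeLines(c("name,abbreviation,formula,peaks",
               "x,X,Qq7,1000:1.0:8"), badform)
  expect_error(build_reference_library(badform), "unknown element")

  badpeaks <- tempfile(fileext = ".csv")
  writeLines(c("name,abbreviation,formula,peaks",
               "x,X,C2H5NO2,1000:0.5"), badpeaks)
  expect_error(build_reference_library(badpeaks), "unparseable")
})

test_that("pure spectrum simulator is linear with on-grid apex", {
  g <- test_grid()
  rec <- one_peak_record(1571)
  expect_equal(simulate_pure_spectrum(rec, g, amplitude = 0),
               numeric(g$points))
  y <- simulate_pure_spectrum(rec, g, amplitude = 3.5)
  expect_equal(max(y), 3.5)
  expect_equal(g$axis[which.max(y)], g$axis[nearest_index(g, 1571)])
  # doubling the amplitude doubles the numeric integral over the grid
  y1 <- simulate_pure_spectrum(rec, g, amplitude = 1)
  y2 <- simulate_pure_spectrum(rec, g, amplitude = 2)
  expect_equal(sum(y2) * g$step, 2 * sum(y1) * g$step)
  expect_equal(y2, 2 * y1)
  expect_error(simulate_pure_spectrum(rec, g, amplitude = -1),
               "nonnegative")
})

test_that("sersome generator is seeded, reproducible and degenerates cleanly", {
  g <- test_grid()
  lib <- tiny_library()
  conc <- c(alpha = 1, beta = 0.5)
  frozen <- cell_profile("c1", "g", conc, fluctuation_sigma = 0,
                         baseline = baseline_params(jitter = 0),
                         noise_sigma = 0)
  s0 <- simulate_sersome(frozen, lib, g, n_spectra = 5, seed = 1)
  expect_equal(n_spectra(s0), 5)
  # no stochastic terms: all spectra identical
  expect_true(all(apply(s0$intensities, 1, function(r) diff(range(r)) == 0)))

  noisy <- cell_profile("c1", "g", conc)
  a <- simulate_sersome(noisy, lib, g, seed = 7)
  b <- simulate_sersome(noisy, lib, g, seed = 7)
  expect_identical(a$intensities, b$intensities)
  expect_equal(n_spectra(a), 36)  # default matches the 6 x 6 mapping grid
  expect_identical(formals(simulate_sersome)$n_spectra, 6 * 6)

  bad <- cell_profile("c1", "g", c(gamma = 1))
  expect_error(simulate_sersome(bad, lib, g), "unknown metabolite")
})

test_that("averaging more spectra converges to the noiseless expectation", {
  g <- test_grid(step = 8)
  lib <- tiny_library()
  prof <- cell_profile("c1", "g", c(alpha = 1, beta = 0.5))
  truth <- expected_spectrum(prof, lib, g)
  closer <- vapply(1:20, function(sd) {
    big <- simulate_sersome(prof, lib, g, n_spectra = 400, seed = sd)
    small <- simulate_sersome(prof, lib, g, n_spectra = 10, seed = sd + 1000)
    l2 <- function(s) sqrt(sum((rowMeans(s$intensities) - truth)^2))
    l2(big) < l2(small)
  }, logical(1))
  expect_gt(mean(closer), 0.85)
})

test_that("population generator plants the aged 1571 elevation", {
  g <- test_grid()
  lib <- build_reference_library()
  pop <- simulate_population(design = c(young = 39, aged = 118),
                             library = lib, grid = g, n_spectra = 2,
                             seed = 3)
  expect_length(pop, 157)
  labels <- vapply(pop, function(s) s$group, character(1))
  expect_equal(sum(labels == "young"), 39)
  expect_equal(sum(labels == "aged"), 118)

  # aged mean 1571 intensity exceeds young across seeds
  i1571 <- nearest_index(g, 1571)
  wins <- vapply(1:10, function(sd) {
    pop <- simulate_population(design = c(young = 4, aged = 4),
                               library = lib, grid = g, n_spectra = 4,
                               seed = sd)
    m <- vapply(pop, function(s) mean(s$intensities[i1571, ]), numeric(1))
    lab <- vapply(pop, function(s) s$group, character(1))
    mean(m[lab == "aged"]) > mean(m[lab == "young"])
  }, logical(1))
  expect_true(all(wins))

  expect_error(simulate_population(heterogeneity = 0.5), "0.5")
})

test_that("zero heterogeneity draws every young cell from the young profile", {
  g <- test_grid(step = 8)
  lib <- build_reference_library()
  young <- young_profile(lib, fluctuation_sigma = 0,
                         baseline = NULL, noise_sigma = 0)
  aged <- aged_profile(lib, fluctuation_sigma = 0,
                       baseline = NULL, noise_sigma = 0)
  pop <- simulate_population(design = c(young = 6, aged = 2), library = lib,
                             young = young, aged = aged, heterogeneity = 0,
                             cell_sigma = 0, scale_sigma = 0, grid = g,
                             n_spectra = 2, seed = 5)
  truth <- expected_spectrum(young, lib, g)
  for (s in pop[1:6]) {
    expect_equal(s$intensities[, 1], unname(truth), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("droplet occupancy follows Poisson statistics", {
  res <- poisson_occupancy(droplet_spec(1.4, 1.5e6), k_max = 6)
  expect_equal(res$lambda, 2.1)
  expect_equal(res$p[2], 2.1 * exp(-2.1), tolerance = 1e-12)
  expect_equal(sum(res$p) + res$tail, 1, tolerance = 1e-12)
  expect_true(all(res$p >= 0))
  expect_equal(res$k[which.max(res$p)], floor(res$lambda))

  res0 <- poisson_occupancy(droplet_spec(1.4, 0), k_max = 2)
  expect_equal(res0$p[1], 1)
  expect_error(droplet_spec(-1, 1e6), "positive")
  expect_error(droplet_spec(1.4, -1), "nonnegative")
})

test_that("protocol arithmetic reproduces droplet and colloid volumes", {
  expect_equal(merge_droplets(1.4, 1.4), 2.8)
  expect_equal(merge_droplets(1.4, 2.9), 4.3)
  expect_equal(merge_droplets(0.7, 0), 0.7)
  expect_error(merge_droplets(-1, 1), "nonnegative")

  expect_equal(concentrate_colloid(0.2, 1000, 950), 4)
  expect_equal(concentrate_colloid(1, 100, 50), 2)
  expect_equal(concentrate_colloid(0.3, 100, 0), 0.3)
  expect_error(concentrate_colloid(0.2, 100, 100), "v_total")
})
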