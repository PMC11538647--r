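test_that("band intensity extraction follows the configured mode", {
  g <- test_grid(step = 2)
  zero <- numeric(g$points)
  expect_equal(band_intensity(zero, g, 1000), 0)

  y <- simulate_pure_spectrum(one_peak_record(1571), g, amplitude = 2.2)
  expect_equal(band_intensity(y, g, 1571), 2.2)

  # off-apex query: nearest-point reads the grid point, local-max finds the apex
  near <- band_intensity(y, g, 1562)
  expect_lt(near, 2.2)
  expect_equal(near, y[nearest_index(g, 1562)])
  loc <- band_intensity(y, g, 1562, band_set(1562, mode = "local-max",
                                             halfwindow = 10))
  expect_equal(loc, 2.2)
  expect_error(band_intensity(y, g, 5000), "outside grid")
})

test_that("band correlation matrix reflects planted coupling", {
  g <- test_grid(step = 2)
  lib <- tiny_library()
  # both alpha bands (1000 and 1571) driven by one fluctuation weight
  prof <- cell_profile("c", "g", c(alpha = 1), fluctuation_sigma = 0.4,
                       baseline = NULL, noise_sigma = 0)
  s <- simulate_sersome(prof, lib, g, n_spectra = 30, seed = 2)
  rho <- correlation_matrix(s, band_set(c(1000, 1571)))
  expect_equal(dim(rho), c(2, 2))
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), c(`1000` = 1, `1571` = 1))
  expect_equal(rho[1, 2], 1, tolerance = 1e-12)

  # planted correlation rho* = 0.9 between two band amplitudes
  set.seed(5)
  n <- 500
  z <- stats::rnorm(n)
  a <- 0.9 * z + sqrt(1 - 0.81) * stats::rnorm(n)
  mat <- matrix(0.01, nrow = g$points, ncol = n)
  mat[nearest_index(g, 800), ] <- 5 + z
  mat[nearest_index(g, 1200), ] <- 5 + a
  mat <- mat + matrix(stats::rnorm(length(mat), sd = 1e-3), nrow(mat))
  rho <- correlation_matrix(manual_sersome(mat, g), band_set(c(800, 1200)))
  expect_equal(rho["800", "1200"], 0.9, tolerance = 0.05)

  # constant band flagged undefined
  mat2 <- mat; mat2[nearest_index(g, 800), ] <- 3
  rho2 <- correlation_matrix(manual_sersome(mat2, g),
                             band_set(c(800, 1200)))
  expect_true(all(is.na(rho2["800", ])))
  expect_equal(attr(rho2, "undefined"), "800")
})

test_that("correlation network applies strict thresholds via the t-transform", {
  rho <- diag(2); rho[1, 2] <- rho[2, 1] <- 1
  dimnames(rho) <- list(c("a", "b"), c("a", "b"))
  net <- correlation_network(rho, n = 10)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$p, 0)

  rho[1, 2] <- rho[2, 1] <- 0.8   # exactly at the threshold: excluded
  expect_equal(nrow(correlation_network(rho, n = 100)$edges), 0)

  rho[1, 2] <- rho[2, 1] <- 0.9   # t = 12.04 at n = 36
  net <- correlation_network(rho, n = 36)
  expect_equal(nrow(net$edges), 1)
  tstat <- 0.9 * sqrt((36 - 2) / (1 - 0.81))
  expect_equal(tstat, 12.04, tolerance = 0.01)
  expect_equal(net$edges$p, 2 * stats::pt(-tstat, 34))
  expect_lt(net$edges$p, 1e-12)

  expect_error(correlation_network(rho, n = 3), "n >= 4")
})

test_that("network edge set shrinks monotonically in the rho threshold", {
  set.seed(3)
  m <- 8
  base <- matrix(stats::rnorm(200 * m), 200, m)
  base[, 2] <- base[, 1] * 0.95 + stats::rnorm(200, sd = 0.2)
  base[, 3] <- base[, 1] * 0.9 + stats::rnorm(200, sd = 0.4)
  colnames(base) <- paste0("b", 1:m)
  rho <- stats::cor(base)
  sizes <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(r)
    nrow(correlation_network(rho, n = 200, rho_min = r)$edges), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

# small planted-difference population in feature-matrix form
planted_population <- function(seed, n_cells = 6, n_spec = 4, step = 8,
                               effect = 1) {
  g <- test_grid(step = step)
  lib <- build_reference_library()
  young <- young_profile(lib)
  aged <- aged_profile(lib)
  pop <- simulate_population(design = c(young = n_cells, aged = n_cells),
                             library = lib, young = young, aged = aged,
                             heterogeneity = 0, grid = g,
                             n_spectra = n_spec, seed = seed)
  pm <- population_matrix(pop)
  pm
}

test_that("screening ranks a band differing between classes first", {
  # two classes that differ only through a single-band marker metabolite
  g <- test_grid(step = 8)
  path <- tempfile(fileext = ".csv")
  writeLines(c("name,abbreviation,formula,peaks",
               "marker,Mk,C10H26N4,1571:1.0:8",
               "filler,Fl,C2H5NO2,1000:1.0:8"), path)
  lib2 <- build_reference_library(path)
  lo <- cell_profile("lo", "young", c(marker = 0.5, filler = 1))
  hi <- cell_profile("hi", "aged", c(marker = 2, filler = 1))
  pop <- simulate_population(design = c(young = 8, aged = 8),
                             library = lib2, young = lo, aged = hi,
                             heterogeneity = 0, scale_sigma = 0,
                             grid = g, n_spectra = 4, seed = 1)
  pm <- population_matrix(pop)
  rep1 <- rf_screen(pm$x, pm$label, pm$cell_id, trees = 150, folds = 4,
                    repeats = 2, seed = 11)
  expect_equal(sum(rep1$features$contribution), 100, tolerance = 1e-9)
  expect_lte(abs(rep1$features$shift[1] - 1571), g$step)
  expect_true(any(abs(selected_shifts(rep1) - 1571) <= g$step))

  # deterministic under a fixed master seed
  rep2 <- rf_screen(pm$x, pm$label, pm$cell_id, trees = 150, folds = 4,
                    repeats = 2, seed = 11)
  expect_identical(rep1$features, rep2$features)
  expect_identical(rep1$accuracy, rep2$accuracy)
})

test_that("screening recovery is stable across master seeds", {
  hits <- vapply(1:10, function(sd) {
    pm <- planted_population(seed = sd, n_cells = 6, n_spec = 3,
                             step = 8)
    rep <- rf_screen(pm$x, pm$label, pm$cell_id, trees = 100, folds = 3,
                     repeats = 1, seed = sd)
    sel <- selected_shifts(rep)
    any(abs(sel - 1571) <= pm$grid$step)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("permuted labels give chance-level CV accuracy", {
  pm <- planted_population(seed = 2, n_cells = 8, n_spec = 4)
  set.seed(99)
  # permute labels at the cell level so grouping stays coherent
  cell_lab <- tapply(pm$label, pm$cell_id, `[`, 1)
  perm_cell <- stats::setNames(sample(as.vector(cell_lab)), names(cell_lab))
  rep <- rf_screen(pm$x, perm_cell[pm$cell_id], pm$cell_id, trees = 100,
                   folds = 3, repeats = 3, seed = 7)
  expect_gte(mean(rep$accuracy), 0.4 - 0.05)
  expect_lte(mean(rep$accuracy), 0.6 + 0.05)
})

test_that("a perfectly separating feature dominates the importance ranking", {
  set.seed(4)
  n <- 60
  x <- matrix(stats::rnorm(n * 20), n, 20)
  colnames(x) <- sprintf("wn_%d", seq(500, by = 10, length.out = 20))
  lab <- rep(c("a", "b"), each = n / 2)
  x[, 5] <- ifelse(lab == "a", 0, 1) + stats::rnorm(n, sd = 0.01)
  rep <- rf_screen(x, lab, trees = 100, folds = 5, repeats = 1, seed = 3)
  expect_equal(rep$features$feature[1], colnames(x)[5])
  expect_gt(rep$features$contribution[1],
            max(rep$features$contribution[-1]) * 3)
})

test_that("screening validates class structure", {
  pm <- planted_population(seed = 3, n_cells = 3, n_spec = 2)
  expect_error(rf_screen(pm$x, pm$label, pm$cell_id, folds = 10),
               "fewer cells")
  expect_error(rf_screen(pm$x, rep("one", nrow(pm$x)), pm$cell_id,
                         folds = 2), "two classes")
})

test_that("group comparison produces classical statistics and stars", {
  same <- list(a = c(1, 1, 1, 1), b = c(1, 1, 1, 1))
  res <- compare_band(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$stars, "ns")

  set.seed(6)
  far <- list(a = stats::rnorm(4, 0, 1e-4), b = stats::rnorm(4, 1, 1e-4))
  res <- compare_band(far)
  expect_lt(res$p, 1e-4)
  expect_equal(res$stars, "****")
  expect_match(res$test, "t-test")

  three <- list(a = 1:4, b = 2:5, c = c(1, 3, 2, 4))
  expect_match(compare_band(three)$test, "ANOVA")
  expect_error(compare_band(list(a = 1, b = 1:3)), "at least two")

  expect_equal(p_stars(0.05), "ns")
  expect_equal(p_stars(0.049), "*")
  expect_equal(p_stars(0.0099), "**")
  expect_equal(p_stars(9e-4), "***")
})

test_that("one-way ANOVA holds its nominal type-I error", {
  set.seed(8)
  rejections <- vapply(1:1000, function(i) {
    groups <- list(a = stats::rnorm(6), b = stats::rnorm(6),
                   c = stats::rnorm(6))
    compare_band(groups)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
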