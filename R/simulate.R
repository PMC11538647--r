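#' Simulate the SERS spectrum of a pure metabolite
#'
#' Renders a metabolite record as a sum of Lorentzian lines on the grid,
#' optionally adding a smooth baseline and white Gaussian noise. Peak
#' centres are quantised to the nearest grid point, so a line's apex sits
#' exactly on the acquisition grid (the grid is the resolution limit of the
#' simulated instrument).
#'
#' @param record A metabolite record (element of
#'   `build_reference_library()$records`), or any list with a `peaks` data
#'   frame with columns `shift`, `amp`, `width`.
#' @param grid A [spectral_grid()].
#' @param amplitude Nonnegative scalar scaling the whole peak set.
#' @param baseline Optional baseline parameter list as produced by
#'   [baseline_params()], or `NULL` for no baseline.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Optional integer seed (only used when noise is drawn).
#'
#' @return Numeric intensity vector of length `grid$points`.
#' @export
simulate_pure_spectrum <- function(record, grid, amplitude = 1,
                                   baseline = NULL, noise_sigma = 0,
                                   seed = NULL) {
  stopifnot_grid(grid)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    stop("amplitude must be a nonnegative scalar")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  y <- amplitude * pure_profile(record, grid)
  if (!is.null(baseline)) y <- y + eval_baseline(baseline, grid)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(grid$points, sd = noise_sigma)
  }
  y
}

# Unit-amplitude Lorentzian profile of one record; apex of each line is its
# relative amplitude, centred on the nearest grid point.
pure_profile <- function(record, grid) {
  peaks <- record$peaks
  y <- numeric(grid$points)
  for (j in seq_len(nrow(peaks))) {
    centre <- grid$axis[nearest_index(grid, peaks$shift[j])]
    w <- peaks$width[j]
    y <- y + peaks$amp[j] * w^2 / ((grid$axis - centre)^2 + w^2)
  }
  y
}

#' Baseline parameter set
#'
#' The simulated background is a broad low-order polynomial plus an
#' exponential decay toward high wavenumber, the shape typically left by
#' quartz/colloid background and residual fluorescence. Per-spectrum
#' amplitude jitter is multiplicative log-normal.
#'
#' @param b0,b1,b2 Polynomial coefficients over the normalised axis
#'   `u = (wavenumber - start) / (stop - start)`.
#' @param b_exp Amplitude of the exponential term `b_exp * exp(-u / tau)`.
#' @param tau Decay constant of the exponential term (normalised units).
#' @param jitter Log-normal sigma of the per-spectrum amplitude jitter.
#' @return A named list of class `baseline_params`.
#' @export
baseline_params <- function(b0 = 0.8, b1 = -0.4, b2 = 0.3, b_exp = 1.5,
                            tau = 0.35, jitter = 0.03) {
  structure(list(b0 = b0, b1 = b1, b2 = b2, b_exp = b_exp, tau = tau,
                 jitter = jitter), class = "baseline_params")
}

eval_baseline <- function(bl, grid) {
  u <- (grid$axis - grid$start) / (grid$stop - grid$start)
  bl$b0 + bl$b1 * u + bl$b2 * u^2 + bl$b_exp * exp(-u / bl$tau)
}

#' Cell profile for the SERSome generator
#'
#' Bundles everything that defines the simulated lysate of one cell: the
#' metabolite abundances, the hotspot fluctuation level, the baseline
#' family and the noise level.
#'
#' @param cell_id Cell identifier.
#' @param group Group label.
#' @param concentrations Named numeric vector of nonnegative metabolite
#'   abundances (arbitrary units); names must be library metabolite names.
#' @param fluctuation_sigma Log-normal sigma of the per-(spectrum,
#'   metabolite) hotspot fluctuation weights (mean-1 log-normal).
#' @param baseline A [baseline_params()] list, or `NULL`.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @return A list of class `cell_profile`.
#' @export
cell_profile <- function(cell_id, group, concentrations,
                         fluctuation_sigma = 0.22,
                         baseline = baseline_params(),
                         noise_sigma = 0.02) {
  if (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))) {
    stop("concentrations must be a named vector")
  }
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (fluctuation_sigma < 0 || noise_sigma < 0) stop("sigmas must be >= 0")
  structure(
    list(cell_id = as.character(cell_id), group = as.character(group),
         concentrations = concentrations,
         fluctuation_sigma = fluctuation_sigma,
         baseline = baseline, noise_sigma = noise_sigma),
    class = "cell_profile"
  )
}

#' Default young / aged fibroblast profiles
#'
#' The aged profile elevates the 12 metabolites carrying the 1571 cm^-1
#' band, with spermine raised the most; all other abundances match the
#' young profile. Abundances are arbitrary units.
#'
#' @param library A `reference_library`.
#' @param cell_id,group Passed to [cell_profile()].
#' @param ... Further arguments passed to [cell_profile()].
#' @return A `cell_profile`.
#' @export
young_profile <- function(library, cell_id = "young", group = "young", ...) {
  conc <- base_concentrations(library)
  conc["spermine"] <- 0.4
  cell_profile(cell_id, group, conc, ...)
}

#' @rdname young_profile
#' @export
aged_profile <- function(library, cell_id = "aged", group = "aged", ...) {
  conc <- base_concentrations(library)
  carriers <- names(which(which_band_carriers(library, 1571)))
  conc[carriers] <- 1.6
  conc["spermine"] <- 2.5
  cell_profile(cell_id, group, conc, ...)
}

base_concentrations <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  stats::setNames(rep(1, length(library$records)), names(library$records))
}

# Named logical vector: which library records have a peak within tol of shift.
which_band_carriers <- function(library, shift, tol = 5) {
  vapply(library$records,
         function(r) any(abs(r$peaks$shift - shift) <= tol),
         logical(1))
}

#' Simulate one SERSome
#'
#' Generates `n_spectra` fluctuating spectra from a cell profile. Spectrum
#' i is `sum_m c_m * w_im * pure_m + baseline_i + noise_i`, where the
#' hotspot weights `w_im` are independent mean-1 log-normal draws per
#' spectrum and metabolite (stochastic hotspot occupancy), the baseline is
#' the profile's baseline shape with per-spectrum log-normal amplitude
#' jitter, and the noise is white Gaussian.
#'
#' @param profile A [cell_profile()].
#' @param library A `reference_library`; every concentration name must be a
#'   library metabolite.
#' @param grid A [spectral_grid()].
#' @param n_spectra Number of spectra; the default 36 matches a 6 x 6
#'   mapping acquisition.
#' @param seed Optional integer seed; identical seeds and parameters give
#'   bit-identical SERSomes.
#' @return A [sersome()].
#' @export
simulate_sersome <- function(profile, library, grid = spectral_grid(),
                             n_spectra = 36, seed = NULL) {
  stopifnot(inherits(profile, "cell_profile"),
            inherits(library, "reference_library"))
  stopifnot_grid(grid)
  if (n_spectra < 2) stop("n_spectra must be >= 2")
  unknown <- setdiff(names(profile$concentrations), names(library$records))
  if (length(unknown)) {
    stop("unknown metabolite(s) in profile: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  conc <- profile$concentrations
  m <- length(conc)
  pure <- vapply(names(conc),
                 function(nm) pure_profile(library$records[[nm]], grid),
                 numeric(grid$points))
  sig <- profile$fluctuation_sigma
  # mean-1 log-normal: meanlog = -sig^2/2
  w <- if (sig > 0) {
    matrix(stats::rlnorm(n_spectra * m, meanlog = -sig^2 / 2, sdlog = sig),
           nrow = m, ncol = n_spectra)
  } else {
    matrix(1, nrow = m, ncol = n_spectra)
  }
  intens <- pure %*% (conc * w)
  if (!is.null(profile$baseline)) {
    shape <- eval_baseline(profile$baseline, grid)
    jit <- profile$baseline$jitter
    amp <- if (jit > 0) {
      stats::rlnorm(n_spectra, meanlog = -jit^2 / 2, sdlog = jit)
    } else rep(1, n_spectra)
    intens <- intens + outer(shape, amp)
  }
  if (profile$noise_sigma > 0) {
    intens <- intens + matrix(stats::rnorm(grid$points * n_spectra,
                                           sd = profile$noise_sigma),
                              nrow = grid$points)
  }
  colnames(intens) <- sprintf("%s_%02d", profile$cell_id, seq_len(n_spectra))
  sersome(intens, grid, cell_id = profile$cell_id, group = profile$group,
          meta = list(seed = seed, n_spectra = n_spectra))
}

#' Noiseless expectation of a cell profile's spectrum
#'
#' The mean spectrum the generator converges to: concentration-weighted sum
#' of pure profiles plus the (unjittered) baseline shape.
#'
#' @inheritParams simulate_sersome
#' @return Numeric vector of length `grid$points`.
#' @export
expected_spectrum <- function(profile, library, grid = spectral_grid()) {
  pure <- vapply(names(profile$concentrations),
                 function(nm) pure_profile(library$records[[nm]], grid),
                 numeric(grid$points))
  y <- drop(pure %*% profile$concentrations)
  if (!is.null(profile$baseline)) y <- y + eval_baseline(profile$baseline, grid)
  y
}

#' Simulate a two-group single-cell population
#'
#' Draws SERSomes for a young and an aged group. Each cell's abundances are
#' its group profile's abundances with multiplicative per-cell log-normal
#' jitter (cell-to-cell heterogeneity); a fraction of the young cells is
#' drawn from the aged profile instead (cells with an aged-like metabolic
#' state), while keeping the nominal `young` label.
#'
#' @param design Named counts per group, e.g. `c(young = 39, aged = 118)`.
#'   The default matches one young fibroblast line (39 cells) and three
#'   aged lines totalling 118 cells.
#' @param young,aged The two group [cell_profile()]s; defaults are
#'   [young_profile()] / [aged_profile()] over `library`.
#' @param heterogeneity Fraction (in `[0, 0.5)`) of young cells drawn from
#'   the aged profile.
#' @param cell_sigma Log-normal sigma of the per-cell, per-metabolite
#'   abundance jitter.
#' @param scale_sigma Log-normal sigma of a per-cell global intensity
#'   scale (cell-to-cell variation in size and metabolite release); it
#'   multiplies every abundance of the cell by one shared draw.
#' @param library,grid,n_spectra,seed As in [simulate_sersome()].
#' @return List of [sersome()] objects, one per cell.
#' @export
simulate_population <- function(design = c(young = 39, aged = 118),
                                library = build_reference_library(),
                                young = young_profile(library),
                                aged = aged_profile(library),
                                heterogeneity = 0.1, cell_sigma = 0.1,
                                scale_sigma = 0.25,
                                grid = spectral_grid(), n_spectra = 36,
                                seed = NULL) {
  if (length(design) != 2L || is.null(names(design))) {
    stop("design must be a named vector of two group counts")
  }
  if (any(design < 1)) stop("need at least one cell per group")
  if (heterogeneity < 0 || heterogeneity >= 0.5) {
    stop("heterogeneity fraction must be in [0, 0.5)")
  }
  if (!is.null(seed)) set.seed(seed)
  n_young <- design[[1]]; n_aged <- design[[2]]
  g_young <- names(design)[1]; g_aged <- names(design)[2]
  n_mixed <- floor(heterogeneity * n_young)
  mixed_idx <- if (n_mixed > 0) sample(n_young, n_mixed) else integer(0)
  draw_cell <- function(profile, id, label) {
    conc <- profile$concentrations
    if (cell_sigma > 0) {
      conc <- conc * stats::rlnorm(length(conc), meanlog = -cell_sigma^2 / 2,
                                   sdlog = cell_sigma)
    }
    if (scale_sigma > 0) {
      conc <- conc * stats::rlnorm(1, meanlog = -scale_sigma^2 / 2,
                                   sdlog = scale_sigma)
    }
    p <- cell_profile(id, label, conc,
                      fluctuation_sigma = profile$fluctuation_sigma,
                      baseline = profile$baseline,
                      noise_sigma = profile$noise_sigma)
    simulate_sersome(p, library, grid, n_spectra = n_spectra)
  }
  cells <- vector("list", n_young + n_aged)
  for (i in seq_len(n_young)) {
    src <- if (i %in% mixed_idx) aged else young
    cells[[i]] <- draw_cell(src, sprintf("%s%03d", g_young, i), g_young)
  }
  for (i in seq_len(n_aged)) {
    cells[[n_young + i]] <- draw_cell(aged, sprintf("%s%03d", g_aged, i),
                                      g_aged)
  }
  cells
}
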