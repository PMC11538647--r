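#' Uniform Raman-shift axis
#'
#' Constructs the wavenumber grid shared by every spectrum in a run. The
#' default covers 400--1800 cm^-1 at 2 cm^-1 spacing, which spans all
#' metabolite bands handled by the packaged reference library.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber bound (cm^-1); the axis stops at the largest
#'   grid point `start + k * step <= stop`.
#' @param step Grid spacing (cm^-1), must be positive.
#'
#' @return An object of class `spectral_grid`: a list with elements
#'   `start`, `stop`, `step`, `points` and the numeric `axis`.
#' @examples
#' g <- spectral_grid()
#' g$points
#' @export
spectral_grid <- function(start = 400, stop = 1800, step = 2) {
  if (!is.numeric(start) || !is.numeric(stop) || !is.numeric(step) ||
      length(start) != 1L || length(stop) != 1L || length(step) != 1L) {
    stop("start, stop and step must be scalar numerics")
  }
  if (!(start < stop)) stop("start must be strictly less than stop")
  if (step <= 0) stop("step must be positive")
  points <- floor((stop - start) / step) + 1L
  axis <- start + step * (seq_len(points) - 1L)
  structure(
    list(start = start, stop = stop, step = step,
         points = as.integer(points), axis = axis),
    class = "spectral_grid"
  )
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g cm^-1, step %g cm^-1 (%d points)\n",
              x$start, x$axis[x$points], x$step, x$points))
  invisible(x)
}

#' @export
length.spectral_grid <- function(x) x$points

is_spectral_grid <- function(x) inherits(x, "spectral_grid")

stopifnot_grid <- function(grid) {
  if (!is_spectral_grid(grid)) stop("'grid' must be a spectral_grid object")
  invisible(grid)
}

#' Index of the grid point nearest a wavenumber
#'
#' @param grid A [spectral_grid()].
#' @param shift Wavenumber(s) in cm^-1; must lie within the grid range.
#' @return Integer index (vectorised over `shift`).
#' @export
nearest_index <- function(grid, shift) {
  stopifnot_grid(grid)
  rng <- range(grid$axis)
  if (any(shift < rng[1] | shift > rng[2])) {
    stop(sprintf("shift outside grid range [%g, %g]", rng[1], rng[2]))
  }
  idx <- round((shift - grid$start) / grid$step) + 1L
  pmin(pmax(as.integer(idx), 1L), grid$points)
}
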