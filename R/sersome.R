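#' SERSome container
#'
#' A SERSome is the ordered set of fluctuating SERS spectra acquired from a
#' single droplet (one cell). Spectra are stored as a matrix with one row
#' per grid point and one column per spectrum; ensemble statistics over the
#' columns represent the metabolic profile of the cell.
#'
#' @param intensities Numeric matrix, `grid$points` rows, one column per
#'   spectrum.
#' @param grid The shared [spectral_grid()].
#' @param cell_id Cell identifier.
#' @param group Group label (e.g. `"young"` or `"aged"`).
#' @param meta Optional named list of extra metadata (cell line tag, seed).
#'
#' @return An object of class `sersome`.
#' @export
sersome <- function(intensities, grid, cell_id = "cell",
                    group = NA_character_, meta = list()) {
  stopifnot_grid(grid)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != grid$points) {
    stop("intensity matrix must have one row per grid point")
  }
  if (!all(is.finite(intensities))) stop("non-finite intensities")
  structure(
    list(intensities = intensities, grid = grid,
         cell_id = as.character(cell_id), group = as.character(group),
         meta = meta),
    class = "sersome"
  )
}

#' @export
print.sersome <- function(x, ...) {
  cat(sprintf("<sersome> cell '%s' (group: %s): %d spectra on %d grid points\n",
              x$cell_id, x$group, n_spectra(x), x$grid$points))
  invisible(x)
}

#' Number of spectra in a SERSome
#' @param x A `sersome`.
#' @return Integer count.
#' @export
n_spectra <- function(x) {
  stopifnot(inherits(x, "sersome"))
  ncol(x$intensities)
}

#' @export
as.matrix.sersome <- function(x, ...) x$intensities

#' Plot the spectra of a SERSome
#'
#' Draws every spectrum (grey) with the pointwise mean overlaid.
#'
#' @param x A `sersome`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sersome <- function(x, ...) {
  graphics::matplot(x$grid$axis, x$intensities, type = "l", lty = 1,
                    col = grDevices::grey(0.75),
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Intensity (a.u.)",
                    main = sprintf("SERSome: %s", x$cell_id), ...)
  graphics::lines(x$grid$axis, rowMeans(x$intensities), col = "firebrick",
                  lwd = 2)
  invisible(x)
}
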