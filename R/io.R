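#' Write a set of SERSomes to CSV
#'
#' One spectra table for the whole run: first column `wavenumber`, then
#' one column per spectrum named `cellid_specindex`; plus a companion
#' metadata table (cell id, group, spectrum count, seed).
#'
#' @param cells List of [sersome()] objects on one shared grid.
#' @param spectra_csv,meta_csv Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_sersomes <- function(cells, spectra_csv, meta_csv) {
  stopifnot(length(cells) >= 1)
  grid <- cells[[1]]$grid
  mats <- lapply(cells, function(s) {
    stopifnot(identical(s$grid$axis, grid$axis))
    s$intensities
  })
  tab <- data.frame(wavenumber = grid$axis, do.call(cbind, mats),
                    check.names = FALSE)
  utils::write.csv(tab, spectra_csv, row.names = FALSE)
  meta <- data.frame(
    cell_id = vapply(cells, function(s) s$cell_id, character(1)),
    group = vapply(cells, function(s) s$group, character(1)),
    n_spectra = vapply(cells, n_spectra, integer(1)),
    seed = vapply(cells, function(s) {
      sd <- s$meta$seed
      if (is.null(sd)) NA_integer_ else as.integer(sd)
    }, integer(1))
  )
  utils::write.csv(meta, meta_csv, row.names = FALSE)
  invisible(list(spectra = spectra_csv, meta = meta_csv))
}

#' Read SERSomes written by [write_sersomes()]
#'
#' @param spectra_csv,meta_csv Paths written by [write_sersomes()].
#' @return List of [sersome()] objects.
#' @export
read_sersomes <- function(spectra_csv, meta_csv) {
  tab <- utils::read.csv(spectra_csv, check.names = FALSE)
  meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  wn <- tab[[1]]
  steps <- diff(wn)
  if (length(unique(round(steps, 9))) != 1L) {
    stop("non-uniform wavenumber axis in spectra table")
  }
  grid <- spectral_grid(wn[1], wn[length(wn)] + steps[1] / 2, steps[1])
  spectra <- as.matrix(tab[, -1, drop = FALSE])
  owner <- sub("_[0-9]+$", "", colnames(spectra))
  lapply(seq_len(nrow(meta)), function(i) {
    cols <- owner == meta$cell_id[i]
    if (!any(cols)) {
      stop(sprintf("no spectra found for cell '%s'", meta$cell_id[i]))
    }
    sersome(spectra[, cols, drop = FALSE], grid,
            cell_id = meta$cell_id[i], group = meta$group[i],
            meta = list(seed = meta$seed[i]))
  })
}
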