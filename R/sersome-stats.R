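#' Pearson correlation coefficient of two spectra
#'
#' Standard product-moment correlation, used both for spectral-set
#' convergence and for band-pair co-fluctuation signatures.
#'
#' @param x,y Numeric vectors of equal length (>= 2) with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("need at least two points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(x, y)
}

#' Pointwise mean and standard deviation of a SERSome
#'
#' @param x A [sersome()] with at least two spectra.
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
mean_spectrum <- function(x) {
  stopifnot(inherits(x, "sersome"))
  if (n_spectra(x) < 2) stop("need >= 2 spectra for mean and sd")
  list(mean = rowMeans(x$intensities),
       sd = apply(x$intensities, 1, stats::sd))
}

#' PCC convergence curve of a SERSome
#'
#' Quantifies how many spectra a SERSome needs for a statistically stable
#' metabolic profile: for each subset size `s`, two disjoint `s`-subsets of
#' the spectra are drawn at random, each is averaged, and the Pearson
#' correlation of the two averages is recorded; the per-size mean over
#' `n_draws` draws (with a 5-95 percentile band) is reported. Disjointness
#' is enforced so shared spectra cannot inflate the correlation.
#'
#' @param x A [sersome()].
#' @param subset_sizes Strictly increasing sizes `s` with `2s <=`
#'   `n_spectra(x)`. Default `seq(2, n/2, by = 2)`.
#' @param n_draws Random subset pairs per size.
#' @param seed Optional integer seed.
#' @return An object of class `pcc_curve`: a data frame with columns
#'   `size`, `total` (`2s`), `mean_pcc`, `q05`, `q95`, plus attributes
#'   `n_draws` and `seed`.
#' @export
pcc_convergence <- function(x, subset_sizes = NULL, n_draws = 200,
                            seed = NULL) {
  stopifnot(inherits(x, "sersome"))
  n <- n_spectra(x)
  if (n < 4) stop("need at least 4 spectra for two disjoint subsets")
  if (is.null(subset_sizes)) subset_sizes <- seq(2, n %/% 2, by = 2)
  if (any(diff(subset_sizes) <= 0)) {
    stop("subset_sizes must be strictly increasing")
  }
  if (any(2 * subset_sizes > n)) {
    stop("each subset size s must satisfy 2s <= number of spectra")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  intens <- x$intensities
  stats_per_size <- lapply(subset_sizes, function(s) {
    pcc <- vapply(seq_len(n_draws), function(i) {
      idx <- sample(n, 2 * s)
      a <- rowMeans(intens[, idx[seq_len(s)], drop = FALSE])
      b <- rowMeans(intens[, idx[s + seq_len(s)], drop = FALSE])
      pearson_cc(a, b)
    }, numeric(1))
    c(mean = mean(pcc), stats::quantile(pcc, c(0.05, 0.95)))
  })
  out <- data.frame(size = subset_sizes, total = 2 * subset_sizes,
                    mean_pcc = vapply(stats_per_size, `[[`, numeric(1), 1),
                    q05 = vapply(stats_per_size, `[[`, numeric(1), 2),
                    q95 = vapply(stats_per_size, `[[`, numeric(1), 3))
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  class(out) <- c("pcc_curve", "data.frame")
  out
}

#' Minimum number of spectra for a stable SERSome
#'
#' Reads a convergence curve off at a PCC threshold: the smallest total
#' spectrum count `2s` whose mean PCC reaches the threshold (no
#' interpolation between listed sizes).
#'
#' @param curve A `pcc_curve` from [pcc_convergence()].
#' @param threshold Mean-PCC threshold (default 0.999).
#' @return The total spectrum count, or `NA_integer_` (with a warning) if
#'   the threshold is never reached.
#' @export
minimum_spectra <- function(curve, threshold = 0.999) {
  stopifnot(inherits(curve, "pcc_curve"))
  if (nrow(curve) == 0L) stop("empty convergence curve")
  hit <- which(curve$mean_pcc >= threshold)
  if (!length(hit)) {
    warning(sprintf("not converged: mean PCC never reaches %g", threshold))
    return(NA_integer_)
  }
  as.integer(curve$total[hit[1]])
}

#' @export
plot.pcc_curve <- function(x, threshold = 0.999, ...) {
  graphics::plot(x$total, x$mean_pcc, type = "b", pch = 16,
                 xlab = "Total spectra (2s)", ylab = "Mean PCC",
                 ylim = range(c(x$q05, x$q95, threshold)), ...)
  graphics::arrows(x$total, x$q05, x$total, x$q95, angle = 90, code = 3,
                   length = 0.03, col = "grey50")
  graphics::abline(h = threshold, lty = 2, col = "firebrick")
  invisible(x)
}
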