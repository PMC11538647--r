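#' Band set for intensity extraction
#'
#' @param shifts Raman shifts (cm^-1) to extract.
#' @param mode `"nearest"`: intensity at the nearest grid point;
#'   `"local-max"`: maximum within `shift +/- halfwindow`.
#' @param halfwindow Half window (cm^-1) for `"local-max"` mode.
#' @return A list of class `band_set`.
#' @export
band_set <- function(shifts, mode = c("nearest", "local-max"),
                     halfwindow = 8) {
  mode <- match.arg(mode)
  if (halfwindow < 0) stop("halfwindow must be >= 0")
  structure(list(shifts = shifts, mode = mode, halfwindow = halfwindow),
            class = "band_set")
}

#' Intensity of a spectrum at a Raman band
#'
#' @param y Numeric intensity vector on `grid`.
#' @param grid The [spectral_grid()].
#' @param shift Band position (cm^-1), inside the grid range.
#' @param bands A [band_set()] providing the extraction mode (its `shifts`
#'   field is ignored here).
#' @return Scalar intensity.
#' @export
band_intensity <- function(y, grid, shift, bands = band_set(shift)) {
  stopifnot_grid(grid)
  if (bands$mode == "nearest") {
    y[nearest_index(grid, shift)]
  } else {
    lo <- max(shift - bands$halfwindow, grid$axis[1])
    hi <- min(shift + bands$halfwindow, grid$axis[grid$points])
    max(y[grid$axis >= lo & grid$axis <= hi])
  }
}

#' Band intensities of every spectrum in a set
#'
#' @param x A [sersome()] or an intensity matrix (one column per spectrum).
#' @param bands A [band_set()].
#' @param grid Required when `x` is a bare matrix.
#' @return Numeric matrix, spectra in rows, one column per band shift.
#' @export
band_matrix <- function(x, bands, grid = NULL) {
  if (inherits(x, "sersome")) {
    grid <- x$grid
    x <- x$intensities
  }
  stopifnot_grid(grid)
  out <- vapply(bands$shifts, function(s) {
    apply(x, 2, band_intensity, grid = grid, shift = s, bands = bands)
  }, numeric(ncol(x)))
  colnames(out) <- as.character(bands$shifts)
  out
}

#' Band-pair correlation matrix of a spectral set
#'
#' Pairwise Pearson correlations of band intensities across the spectra of
#' a set. The matrix is the metabolic co-fluctuation signature: strongly
#' positive pairs track metabolites that fluctuate together (shared
#' hotspots or shared metabolic origin), strongly negative pairs track
#' opposed intensity changes.
#'
#' @param x A [sersome()] (>= 3 spectra) or an intensity matrix with one
#'   column per spectrum (then supply `grid`).
#' @param bands A [band_set()] with at least two shifts.
#' @param grid Required when `x` is a bare matrix.
#' @return Correlation matrix with band shifts as dimnames; bands constant
#'   across spectra give `NA` rows/columns and are listed in the
#'   `undefined` attribute.
#' @export
correlation_matrix <- function(x, bands, grid = NULL) {
  bm <- band_matrix(x, bands, grid)
  if (nrow(bm) < 3) stop("need at least 3 spectra")
  if (ncol(bm) < 2) stop("need at least 2 bands")
  sds <- apply(bm, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(bm))
  if (any(sds == 0)) {
    rho[sds == 0, ] <- NA_real_
    rho[, sds == 0] <- NA_real_
  }
  diag(rho) <- ifelse(sds == 0, NA_real_, 1)
  attr(rho, "undefined") <- colnames(bm)[sds == 0]
  attr(rho, "n") <- nrow(bm)
  rho
}

#' Thresholded band correlation network
#'
#' Keeps band pairs with correlation strictly above `rho_min` and a
#' two-sided p-value below `alpha`. The p-value uses the t-transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' The threshold applies to signed correlations by default; set
#' `use_abs = TRUE` to admit strong negative edges too.
#'
#' @param rho Correlation matrix (e.g. from [correlation_matrix()]).
#' @param n Sample size (number of spectra) behind the correlations, >= 4.
#' @param rho_min Correlation threshold (strict inequality).
#' @param alpha Significance threshold (strict inequality).
#' @param use_abs Threshold `|rho|` instead of signed `rho`.
#' @return An object of class `correlation_network`: list with `edges`
#'   (data frame `a`, `b`, `rho`, `p`), `nodes`, `rho_min`, `alpha`, `n`.
#' @export
correlation_network <- function(rho, n, rho_min = 0.8, alpha = 0.05,
                                use_abs = FALSE) {
  if (n < 4) stop("need n >= 4 samples for the correlation test")
  nodes <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  keep <- !is.na(r)
  ut <- ut[keep, , drop = FALSE]; r <- r[keep]
  crit <- if (use_abs) abs(r) else r
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  tstat[abs(r) >= 1] <- sign(r[abs(r) >= 1]) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  sel <- crit > rho_min & p < alpha
  edges <- data.frame(a = nodes[ut[sel, 1]], b = nodes[ut[sel, 2]],
                      rho = r[sel], p = p[sel],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$rho), edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, nodes = nodes, rho_min = rho_min,
                 alpha = alpha, n = n),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "<correlation_network> %d nodes, %d edges (rho > %g, p < %g, n = %d)\n",
    length(x$nodes), nrow(x$edges), x$rho_min, x$alpha, x$n))
  invisible(x)
}

#' Flatten a single-cell population into a spectrum feature matrix
#'
#' @param cells List of [sersome()] objects sharing one grid.
#' @return List with `x` (spectra x grid-points matrix), `label` (group
#'   per spectrum), `cell_id` (per spectrum) and `grid`.
#' @export
population_matrix <- function(cells) {
  stopifnot(length(cells) >= 1, all(vapply(cells, inherits, logical(1),
                                           "sersome")))
  grid <- cells[[1]]$grid
  x <- do.call(rbind, lapply(cells, function(s) t(s$intensities)))
  colnames(x) <- sprintf("wn_%g", grid$axis)
  list(x = x,
       label = unlist(lapply(cells, function(s) rep(s$group, n_spectra(s)))),
       cell_id = unlist(lapply(cells, function(s)
         rep(s$cell_id, n_spectra(s)))),
       grid = grid)
}

#' Random-forest screening of discriminative Raman shifts
#'
#' Classifies the pooled spectra of all cells (not per-cell averages) into
#' two groups with a random forest under repeated cross-validation, and
#' scores each Raman shift by its impurity-based importance averaged over
#' all fold fits, rescaled to percent of the total. Shifts contributing
#' more than `threshold` percent form the selected feature set.
#' Cross-validation folds are formed over cells, never over spectra, so
#' spectra of one cell cannot straddle the train/test split.
#'
#' @param x Feature matrix, one row per spectrum (e.g.
#'   `population_matrix()$x`), columns named for their Raman shifts.
#' @param labels Group label per spectrum; exactly two classes.
#' @param cell_ids Cell id per spectrum (fold unit). Defaults to one
#'   pseudo-cell per spectrum.
#' @param trees Trees per forest.
#' @param folds,repeats Cross-validation scheme (default tenfold, repeated
#'   10 times).
#' @param threshold Selection threshold in percent of total contribution.
#' @param seed Integer master seed; per-fit seeds are derived from it, so
#'   results are reproducible.
#' @return An object of class `feature_report`: list with `features`
#'   (data frame `shift`, `contribution`, `selected`, sorted by
#'   decreasing contribution), `accuracy` (per-repeat mean CV accuracy),
#'   `scheme`, `threshold`.
#' @export
rf_screen <- function(x, labels, cell_ids = NULL, trees = 200, folds = 10,
                      repeats = 10, threshold = 0.1, seed = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need two classes for screening")
  if (length(classes) > 2) stop("screening is binary: got more than two classes")
  if (is.null(cell_ids)) cell_ids <- sprintf("s%06d", seq_len(nrow(x)))
  cell_ids <- as.character(cell_ids)
  cell_class <- tapply(labels, cell_ids, function(l) l[1])
  for (cl in classes) {
    if (sum(cell_class == cl) < folds) {
      stop(sprintf("class '%s' has fewer cells (%d) than folds (%d)",
                   cl, sum(cell_class == cl), folds))
    }
  }
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  if (!is.null(seed)) set.seed(seed)
  fit_seeds <- sample.int(.Machine$integer.max, repeats * folds)
  imp <- numeric(ncol(x)); names(imp) <- colnames(x)
  accuracy <- numeric(repeats)
  n_fits <- 0L
  for (r in seq_len(repeats)) {
    fold_of_cell <- grouped_folds(cell_class, folds)
    fold <- fold_of_cell[cell_ids]
    correct <- 0L; total <- 0L
    for (k in seq_len(folds)) {
      test <- fold == k
      fit <- ranger::ranger(
        x = x[!test, , drop = FALSE],
        y = factor(labels[!test], levels = classes),
        num.trees = trees, importance = "impurity",
        seed = fit_seeds[(r - 1L) * folds + k], num.threads = 1L
      )
      pred <- stats::predict(fit, data = x[test, , drop = FALSE],
                             num.threads = 1L)$predictions
      correct <- correct + sum(as.character(pred) == labels[test])
      total <- total + sum(test)
      imp <- imp + fit$variable.importance
      n_fits <- n_fits + 1L
    }
    accuracy[r] <- correct / total
  }
  imp <- imp / n_fits
  contribution <- 100 * imp / sum(imp)
  shifts <- suppressWarnings(as.numeric(sub("^wn_", "", names(imp))))
  features <- data.frame(
    feature = names(imp),
    shift = shifts,
    contribution = unname(contribution),
    selected = unname(contribution > threshold),
    stringsAsFactors = FALSE
  )
  features <- features[order(-features$contribution), , drop = FALSE]
  rownames(features) <- NULL
  structure(
    list(features = features, accuracy = accuracy,
         scheme = sprintf("%d-fold CV x %d repeats, %d trees, grouped by cell",
                          folds, repeats, trees),
         threshold = threshold, classes = classes, seed = seed),
    class = "feature_report"
  )
}

# stratified assignment of cells to folds: each class spread evenly
grouped_folds <- function(cell_class, folds) {
  fold <- integer(length(cell_class))
  names(fold) <- names(cell_class)
  for (cl in unique(cell_class)) {
    idx <- which(cell_class == cl)
    fold[idx[sample.int(length(idx))]] <-
      rep(seq_len(folds), length.out = length(idx))
  }
  fold
}

#' @export
print.feature_report <- function(x, ...) {
  sel <- x$features[x$features$selected, , drop = FALSE]
  cat(sprintf("<feature_report> %s\n", x$scheme))
  cat(sprintf("  classes: %s | mean CV accuracy: %.3f\n",
              paste(x$classes, collapse = " vs "), mean(x$accuracy)))
  cat(sprintf("  %d of %d features selected (contribution > %g%%)\n",
              nrow(sel), nrow(x$features), x$threshold))
  if (nrow(sel)) {
    top <- utils::head(sel, 5)
    cat(sprintf("  top shifts: %s\n",
                paste(sprintf("%g (%.2f%%)", top$shift, top$contribution),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Selected Raman shifts of a feature report
#' @param report A `feature_report`.
#' @return Numeric vector of selected shifts, decreasing contribution.
#' @export
selected_shifts <- function(report) {
  stopifnot(inherits(report, "feature_report"))
  report$features$shift[report$features$selected]
}

#' Group comparison of band intensities
#'
#' Two groups are compared with a two-tailed t-test; more than two with
#' one-way ANOVA. Returns the test statistic, p-value and the
#' conventional star annotation (strict inequalities; `p = 0.05` is "ns").
#'
#' @param groups Named list mapping group label to a numeric sample of
#'   band intensities (>= 2 observations each).
#' @param var_equal Assume equal variances in the t-test (classical
#'   unpaired t-test); set `FALSE` for Welch.
#' @return A list with `test`, `statistic`, `p` and `stars`.
#' @export
compare_band <- function(groups, var_equal = TRUE) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least two observations")
  }
  if (length(groups) == 2) {
    a <- groups[[1]]; b <- groups[[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      statistic <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      ht <- stats::t.test(a, b, var.equal = var_equal)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
    test <- "two-tailed t-test"
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), lengths(groups)))
    ht <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    test <- "one-way ANOVA"
  }
  list(test = test, statistic = statistic, p = p, stars = p_stars(p))
}

#' Significance star annotation
#'
#' @param p p-value.
#' @return `"****"` for p < 0.0001, `"***"` for p < 0.001, `"**"` for
#'   p < 0.01, `"*"` for p < 0.05, otherwise `"ns"`.
#' @export
p_stars <- function(p) {
  if (p < 1e-4) "****"
  else if (p < 1e-3) "***"
  else if (p < 1e-2) "**"
  else if (p < 0.05) "*"
  else "ns"
}
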