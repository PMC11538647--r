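#' 2-D embedding of selected spectral features
#'
#' Projects the rows of a feature matrix to two dimensions for visual
#' validation of class separation. The default method is a principal
#' component projection (centred, optionally scaled), which is exactly
#' deterministic: duplicate rows map to identical coordinates and repeated
#' calls reproduce the layout bit for bit. The silhouette width of the
#' nominal labels on the embedding is reported alongside as a separation
#' score.
#'
#' @param features Numeric matrix, one row per spectrum (or per cell),
#'   columns = selected features.
#' @param labels Optional group label per row, used for the silhouette
#'   score and default plot colours.
#' @param scale Scale columns to unit variance before projection.
#' @param seed Retained for interface stability; the projection itself is
#'   deterministic.
#' @return An object of class `embedding_result`: list with `coords`
#'   (n x 2 matrix), `labels`, `silhouette` (mean silhouette width of the
#'   labels, `NA` without labels), `params`.
#' @export
embed_features <- function(features, labels = NULL, scale = FALSE,
                           seed = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 10) stop("need at least 10 rows to embed")
  if (!is.null(labels) && length(labels) != nrow(features)) {
    stop("labels must match rows of features")
  }
  keep <- apply(features, 2, stats::sd) > 0 | !scale
  pc <- stats::prcomp(features[, keep, drop = FALSE], center = TRUE,
                      scale. = scale, rank. = 2)
  coords <- pc$x
  if (ncol(coords) < 2) coords <- cbind(coords, 0)
  colnames(coords) <- c("dim1", "dim2")
  sil <- NA_real_
  if (!is.null(labels) && length(unique(labels)) > 1) {
    sil <- mean(cluster::silhouette(as.integer(factor(labels)),
                                    stats::dist(coords))[, "sil_width"])
  }
  structure(list(coords = coords, labels = labels, silhouette = sil,
                 params = list(method = "pca", scale = scale, seed = seed)),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points (%s)", nrow(x$coords),
              x$params$method))
  if (!is.na(x$silhouette)) {
    cat(sprintf("; label silhouette %.3f", x$silhouette))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.embedding_result <- function(x, color = NULL, ...) {
  col <- if (!is.null(color)) {
    grDevices::hcl.colors(100, "viridis")[
      cut(color, 100, labels = FALSE, include.lowest = TRUE)]
  } else if (!is.null(x$labels)) {
    as.integer(factor(x$labels)) + 1L
  } else 1L
  graphics::plot(x$coords, col = col, pch = 16, xlab = "Dimension 1",
                 ylab = "Dimension 2", ...)
  invisible(x)
}

#' Agglomerative clustering of feature profiles
#'
#' Ward clustering (on squared Euclidean distances, `ward.D2`) of the rows
#' of a feature matrix, cut into `k` clusters. The leaf order of the
#' dendrogram is exported for heatmap display, and the merge tree can be
#' serialised to Newick text via [ape::as.phylo()].
#'
#' @param features Numeric matrix, one row per observation.
#' @param k Number of clusters for the cut (`<= nrow(features)`).
#' @param method,metric Linkage method and distance metric; the defaults
#'   (`"ward.D2"`, `"euclidean"`) correspond to classical Ward/Euclidean
#'   clustering.
#' @return An object of class `hclust_result`: list with `labels` (cluster
#'   index per row), `hclust` (the merge tree), `order` (leaf order),
#'   `heights`, `k`.
#' @export
hierarchical_cluster <- function(features, k = 2, method = "ward.D2",
                                 metric = "euclidean") {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 rows")
  if (k > nrow(features)) stop("k cannot exceed the number of rows")
  hc <- stats::hclust(stats::dist(features, method = metric),
                      method = method)
  structure(list(labels = stats::cutree(hc, k = k), hclust = hc,
                 order = hc$order, heights = hc$height, k = k),
            class = "hclust_result")
}

#' @export
print.hclust_result <- function(x, ...) {
  cat(sprintf("<hclust_result> %d observations cut at k = %d (%s)\n",
              length(x$labels), x$k, x$hclust$method))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Newick serialisation of a cluster dendrogram
#'
#' @param x A `hclust_result`.
#' @return Newick string (single line).
#' @export
dendrogram_newick <- function(x) {
  stopifnot(inherits(x, "hclust_result"))
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected agreement between a clustering and reference labels
#' (1 = identical partitions, ~0 = random agreement).
#'
#' @param a,b Two label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(1)
  (nij - expected) / (maxidx - expected)
}
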