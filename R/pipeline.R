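#' Default band set for signature analyses
#'
#' The labelled Raman bands used for correlation matrices/networks:
#' S-S (510, 542), C-C twist (624), C-S (650), adenine ring (728), indole/
#' purine breathing (753), C-C (1077), 1150, purine ring (1320), CH (1331),
#' CH2 (1441, 1450), COO- (1560) and C-N/C-C (1571) stretching.
#'
#' @param mode,halfwindow Passed to [band_set()].
#' @return A [band_set()].
#' @export
default_band_set <- function(mode = "nearest", halfwindow = 8) {
  band_set(c(510, 542, 624, 650, 728, 753, 1077, 1150, 1320, 1331,
             1441, 1450, 1560, 1571), mode = mode, halfwindow = halfwindow)
}

# allowed keys per config section
config_schema <- list(
  seed = NULL,
  grid = c("start", "stop", "step"),
  population = c("young", "aged", "n_spectra", "heterogeneity",
                 "cell_sigma", "scale_sigma"),
  preprocess = c("sg_window", "sg_order", "airpls_lambda", "airpls_order",
                 "airpls_max_iter", "airpls_ratio", "normalize"),
  stats = c("draws", "pcc_threshold"),
  screen = c("trees", "folds", "repeats", "threshold"),
  cluster = c("k"),
  match = c("tolerance"),
  report = c("title")
)

#' Default pipeline configuration
#'
#' A moderate problem size intended for interactive runs: 12 + 12 cells
#' with 12 spectra each and a lighter cross-validation scheme than the
#' full protocol (which is restored by raising `population` counts,
#' `n_spectra` to 36 and `screen$folds`/`repeats` to 10).
#'
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    grid = list(start = 400, stop = 1800, step = 2),
    population = list(young = 12, aged = 12, n_spectra = 12,
                      heterogeneity = 0.1, cell_sigma = 0.1,
                      scale_sigma = 0.25),
    preprocess = list(sg_window = 5, sg_order = 3, airpls_lambda = 1e7,
                      airpls_order = 3, airpls_max_iter = 15,
                      airpls_ratio = 0.001, normalize = TRUE),
    stats = list(draws = 200, pcc_threshold = 0.999),
    screen = list(trees = 150, folds = 4, repeats = 2, threshold = 0.1),
    cluster = list(k = 2),
    match = list(tolerance = 5),
    report = list(title = "SERSome single-cell metabolic profiling run")
  ), class = "run_config")
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML config, overlays it on [default_run_config()] and rejects
#' unknown keys before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(config_schema))
    if (length(bad)) stop("unknown config key(s): ",
                          paste(bad, collapse = ", "))
    for (sec in names(user)) {
      if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
      bad <- setdiff(names(user[[sec]]), config_schema[[sec]])
      if (length(bad)) {
        stop(sprintf("unknown key(s) in config section '%s': %s",
                     sec, paste(bad, collapse = ", ")))
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  validate_run_config(cfg)
}

#' Validate a pipeline configuration list
#'
#' Checks group counts, preprocessing parameters and the grid, and stamps
#' the `run_config` class. Called by [read_run_config()] and
#' [run_pipeline()]; useful directly when building configs in code.
#'
#' @param cfg A configuration list shaped like [default_run_config()].
#' @return The validated `run_config`.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$population$young < 1 || cfg$population$aged < 1) {
    stop("need two classes: population counts must both be >= 1")
  }
  if (cfg$population$n_spectra < 2) stop("n_spectra must be >= 2")
  preprocess_config(cfg$preprocess$sg_window, cfg$preprocess$sg_order,
                    cfg$preprocess$airpls_lambda, cfg$preprocess$airpls_order,
                    cfg$preprocess$airpls_max_iter, cfg$preprocess$airpls_ratio,
                    cfg$preprocess$normalize)
  spectral_grid(cfg$grid$start, cfg$grid$stop, cfg$grid$step)
  class(cfg) <- "run_config"
  cfg
}

# Per-stage seeds derived from the master seed with a fixed multiplicative
# congruential step, so one stage's stream never depends on another's.
stage_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + index * 7919) %% 2147483563) + 1L
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> spectral-set statistics ->
#' random-forest screening -> embedding/clustering -> band-to-metabolite
#' matching, writing every stage artifact (CSV), a content-hash manifest,
#' a structured log and a plain-markdown report into `out_dir`. The run is
#' fully deterministic for a fixed config: per-stage seeds derive from
#' `config$seed` and the report body carries no timestamps.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory (created if missing), or `NULL` for a
#'   fresh temporary directory.
#' @return An object of class `sersome_run`: list of stage results plus
#'   `dir` (the artifact directory) and `config`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  config <- validate_run_config(config)
  if (is.null(out_dir)) out_dir <- tempfile("sersome_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }

  grid <- spectral_grid(config$grid$start, config$grid$stop,
                        config$grid$step)
  library <- with_stage("library", build_reference_library())

  # -- simulate ---------------------------------------------------------
  t0 <- proc.time()[3]
  cells <- with_stage("simulate", simulate_population(
    design = c(young = config$population$young,
               aged = config$population$aged),
    library = library, grid = grid,
    heterogeneity = config$population$heterogeneity,
    cell_sigma = config$population$cell_sigma,
    scale_sigma = config$population$scale_sigma %||% 0.25,
    n_spectra = config$population$n_spectra,
    seed = stage_seed(config$seed, 1L)
  ))
  paths <- write_sersomes(cells, file.path(out_dir, "spectra_raw.csv"),
                          file.path(out_dir, "cells.csv"))
  log_line("stage=simulate cells=%d n_spectra=%d seed=%d elapsed=%.2fs",
           length(cells), config$population$n_spectra,
           stage_seed(config$seed, 1L), proc.time()[3] - t0)

  # -- preprocess -------------------------------------------------------
  t0 <- proc.time()[3]
  pcfg <- preprocess_config(config$preprocess$sg_window,
                            config$preprocess$sg_order,
                            config$preprocess$airpls_lambda,
                            config$preprocess$airpls_order,
                            config$preprocess$airpls_max_iter,
                            config$preprocess$airpls_ratio,
                            config$preprocess$normalize)
  pre <- with_stage("preprocess",
                    lapply(cells, preprocess_sersome, config = pcfg))
  write_sersomes(pre, file.path(out_dir, "spectra_preprocessed.csv"),
                 file.path(out_dir, "cells_preprocessed.csv"))
  log_line("stage=preprocess in=%s elapsed=%.2fs",
           basename(paths$spectra), proc.time()[3] - t0)

  # -- spectral-set statistics -----------------------------------------
  t0 <- proc.time()[3]
  curve <- with_stage("sersome_stats", pcc_convergence(
    cells[[1]], n_draws = config$stats$draws,
    seed = stage_seed(config$seed, 2L)))
  min_total <- minimum_spectra(curve, config$stats$pcc_threshold)
  utils::write.csv(as.data.frame(curve),
                   file.path(out_dir, "pcc_curve.csv"), row.names = FALSE)
  log_line("stage=sersome_stats draws=%d min_spectra=%s elapsed=%.2fs",
           config$stats$draws, as.character(min_total),
           proc.time()[3] - t0)

  # -- screening --------------------------------------------------------
  t0 <- proc.time()[3]
  pm <- population_matrix(pre)
  if (length(unique(pm$label)) < 2) {
    stop("stage 'screen' failed: need two classes", call. = FALSE)
  }
  report <- with_stage("screen", rf_screen(
    pm$x, pm$label, pm$cell_id, trees = config$screen$trees,
    folds = config$screen$folds, repeats = config$screen$repeats,
    threshold = config$screen$threshold,
    seed = stage_seed(config$seed, 3L)))
  utils::write.csv(report$features,
                   file.path(out_dir, "feature_contributions.csv"),
                   row.names = FALSE)
  top_band <- top_contribution_band(report)
  log_line("stage=screen top_band=%g acc=%.3f elapsed=%.2fs",
           top_band, mean(report$accuracy), proc.time()[3] - t0)

  # -- group comparison at the top band --------------------------------
  groups <- split(
    vapply(pre, function(s)
      mean(apply(s$intensities, 2, band_intensity, grid = grid,
                 shift = top_band)), numeric(1)),
    vapply(pre, function(s) s$group, character(1)))
  comparison <- with_stage("compare", compare_band(groups))

  # -- correlation networks per group ----------------------------------
  bands <- default_band_set()
  networks <- with_stage("networks", lapply(
    split(pre, vapply(pre, function(s) s$group, character(1))),
    function(cs) {
      bm <- do.call(rbind, lapply(cs, band_matrix, bands = bands))
      rho <- suppressWarnings(stats::cor(bm))
      correlation_network(rho, n = nrow(bm))
    }))
  net_tab <- do.call(rbind, lapply(names(networks), function(g) {
    e <- networks[[g]]$edges
    if (nrow(e)) cbind(group = g, e)
  }))
  if (!is.null(net_tab)) {
    utils::write.csv(net_tab, file.path(out_dir, "networks.csv"),
                     row.names = FALSE)
  }

  # -- embedding and clustering ----------------------------------------
  t0 <- proc.time()[3]
  sel <- selected_shifts(report)
  feat_bands <- band_set(sel[!is.na(sel)])
  # relative-intensity profiles: clustering and embedding should respond to
  # the spectral pattern, not to a cell's overall brightness
  spec_feats <- relative_profiles(
    do.call(rbind, lapply(pre, band_matrix, bands = feat_bands)))
  embedding <- with_stage("embed", embed_features(
    spec_feats, labels = pm$label, seed = stage_seed(config$seed, 4L)))
  cell_feats <- relative_profiles(t(vapply(pre, function(s)
    colMeans(band_matrix(s, feat_bands)),
    numeric(length(feat_bands$shifts)))))
  clustering <- with_stage("cluster",
                           hierarchical_cluster(cell_feats,
                                                k = config$cluster$k))
  ari <- adjusted_rand(clustering$labels,
                       vapply(pre, function(s) s$group, character(1)))
  utils::write.csv(
    data.frame(cell_id = vapply(pre, function(s) s$cell_id, character(1)),
               group = vapply(pre, function(s) s$group, character(1)),
               cluster = clustering$labels),
    file.path(out_dir, "clusters.csv"), row.names = FALSE)
  writeLines(dendrogram_newick(clustering),
             file.path(out_dir, "dendrogram.nwk"))
  log_line("stage=embed_cluster silhouette=%.3f ari=%.3f elapsed=%.2fs",
           embedding$silhouette, ari, proc.time()[3] - t0)

  # -- metabolite matching ---------------------------------------------
  candidates <- with_stage("match", match_band(
    library, top_band, tolerance = config$match$tolerance))
  utils::write.csv(candidates, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  log_line("stage=match band=%g candidates=%d", top_band, nrow(candidates))

  run <- structure(
    list(dir = out_dir, config = config, cells = cells,
         preprocessed = pre, pcc_curve = curve, min_spectra = min_total,
         feature_report = report, top_band = top_band,
         comparison = comparison, networks = networks,
         embedding = embedding, clustering = clustering, ari = ari,
         candidates = candidates),
    class = "sersome_run")
  writeLines(make_report(run), file.path(out_dir, "report.md"))
  manifest <- tools::md5sum(list.files(out_dir, pattern = "\\.(csv|md|nwk)$",
                                       full.names = TRUE))
  utils::write.csv(data.frame(file = basename(names(manifest)),
                              md5 = unname(manifest)),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  run
}

#' Render the run report
#'
#' Produces the plain-markdown report body for a completed run: selected
#' shifts, the top candidate aging band, the group comparison at that
#' band, clustering/embedding summaries and the band-to-metabolite
#' candidate table. Contains no timestamps, so regeneration from the same
#' run is byte-identical.
#'
#' @param run A `sersome_run`.
#' @return Character vector of report lines.
#' @export
make_report <- function(run) {
  stopifnot(inherits(run, "sersome_run"))
  needed <- c("feature_report", "comparison", "clustering", "embedding",
              "candidates")
  for (nm in needed) {
    if (is.null(run[[nm]])) stop(sprintf("missing artifact '%s'", nm))
  }
  cfg <- run$config
  sel <- run$feature_report$features
  sel <- sel[sel$selected, , drop = FALSE]
  lines <- c(
    sprintf("# %s", cfg$report$title),
    "",
    sprintf("Seed: %d | cells: %d young + %d aged | %d spectra/cell",
            cfg$seed, cfg$population$young, cfg$population$aged,
            cfg$population$n_spectra),
    "",
    "## Spectral-set stability",
    "",
    sprintf("Minimum spectra for mean PCC >= %g: %s",
            cfg$stats$pcc_threshold,
            ifelse(is.na(run$min_spectra), "not converged",
                   as.character(run$min_spectra))),
    "",
    "## Discriminative Raman shifts",
    "",
    sprintf("Mean CV accuracy: %.3f (%s)",
            mean(run$feature_report$accuracy), run$feature_report$scheme),
    sprintf("Selected shifts (contribution > %g%%): %s",
            run$feature_report$threshold,
            paste(sprintf("%g", sel$shift), collapse = ", ")),
    sprintf("Top discriminative band: %g cm^-1", run$top_band),
    "",
    "## Group comparison at the top band",
    "",
    sprintf("%s: statistic = %.4g, p = %.3g (%s)",
            run$comparison$test, run$comparison$statistic,
            run$comparison$p, run$comparison$stars),
    "",
    "## Clustering and embedding",
    "",
    sprintf("k = %d cut: adjusted Rand index vs nominal groups = %.3f",
            cfg$cluster$k, run$ari),
    sprintf("Label silhouette on the 2-D embedding: %.3f",
            run$embedding$silhouette),
    "",
    sprintf("## Metabolite candidates at %g cm^-1", run$top_band),
    ""
  )
  if (nrow(run$candidates) == 0L) {
    lines <- c(lines, "No candidates within tolerance.")
  } else {
    lines <- c(lines,
               "| metabolite | abbrev | formula | matched shift | delta |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %s | %g | %g |",
                       run$candidates$name, run$candidates$abbreviation,
                       run$candidates$formula, run$candidates$matched_shift,
                       run$candidates$delta))
  }
  lines
}

#' @export
print.sersome_run <- function(x, ...) {
  cat(sprintf("<sersome_run> %d cells, top band %g cm^-1 (%s), ARI %.3f\n",
              length(x$cells), x$top_band, x$comparison$stars, x$ari))
  cat(sprintf("  artifacts: %s\n", x$dir))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strongest contribution band of a feature report
#'
#' Random-forest importance at single grid points is noisy within a Raman
#' linewidth: adjacent wavenumbers of one band carry nearly identical
#' information and share the contribution mass. The band-level summary
#' therefore sums contributions in a sliding window of `window` cm^-1
#' half-width and returns the contribution-weighted centroid of the
#' strongest window, a stable estimate of the top discriminative band's
#' centre.
#'
#' @param report A `feature_report` whose features are Raman shifts.
#' @param window Half-width (cm^-1) of the aggregation window; the default
#'   is 1.5x the default Lorentzian half-width of the simulator.
#' @return Band centre in cm^-1.
#' @export
top_contribution_band <- function(report, window = 12) {
  stopifnot(inherits(report, "feature_report"))
  f <- report$features[!is.na(report$features$shift), , drop = FALSE]
  if (!nrow(f)) stop("feature report carries no Raman-shift features")
  f <- f[order(f$shift), , drop = FALSE]
  roll <- vapply(f$shift, function(s0)
    sum(f$contribution[abs(f$shift - s0) <= window]), numeric(1))
  s0 <- f$shift[which.max(roll)]
  sel <- abs(f$shift - s0) <= window
  sum(f$shift[sel] * f$contribution[sel]) / sum(f$contribution[sel])
}

#' Row-normalise feature profiles to relative intensity
#'
#' Divides each row by its L1 norm (sum of absolute values), turning
#' absolute band intensities into relative spectral patterns; rows with
#' zero norm are returned unchanged.
#'
#' @param x Numeric matrix, one profile per row.
#' @return Matrix of the same shape.
#' @export
relative_profiles <- function(x) {
  x <- as.matrix(x)
  nrm <- rowSums(abs(x))
  nrm[nrm == 0] <- 1
  x / nrm
}
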