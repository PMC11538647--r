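# Monoisotopic element masses are shipped as a CSV fixture and cached at
# first use.
the <- new.env(parent = emptyenv())

element_masses <- function() {
  if (is.null(the$elements)) {
    path <- system.file("extdata", "element_masses.csv",
                        package = "sersomics", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    the$elements <- stats::setNames(tab$mass, tab$element)
  }
  the$elements
}

ELECTRON_MASS <- 0.000548579909

#' Ion adduct specifications
#'
#' Mass deltas use ion masses (e.g. Na+ as Na minus one electron), so
#' computed m/z values match instrument-printed values at display
#' precision.
#'
#' @param names Subset of `"M+H"`, `"M+Na"`, `"M+K"`, `"M-H"`.
#' @return Data frame with columns `name`, `delta` (Da), `charge`.
#' @export
adduct_specs <- function(names = c("M+H", "M+Na", "M+K", "M-H")) {
  em <- element_masses()
  all <- data.frame(
    name = c("M+H", "M+Na", "M+K", "M-H"),
    delta = c(em[["H"]] - ELECTRON_MASS,
              em[["Na"]] - ELECTRON_MASS,
              em[["K"]] - ELECTRON_MASS,
              -(em[["H"]] - ELECTRON_MASS)),
    charge = c(1L, 1L, 1L, -1L),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(names, all$name)
  if (length(unknown)) stop("unknown adduct(s): ",
                            paste(unknown, collapse = ", "))
  all[match(names, all$name), , drop = FALSE]
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Elemental formula such as `"C10H26N4"`; supported
#'   elements are C, H, N, O, S, P, Na, K and Cl. Counts must be positive
#'   integers (an explicit zero count is rejected).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C10H26N4") # spermine
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stop("formula must be a non-empty string")
  }
  em <- element_masses()
  rx <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(rx))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens) || sum(nchar(tokens)) != nchar(formula)) {
    stop(sprintf("unparseable formula '%s'", formula))
  }
  total <- 0
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(em)) stop(sprintf("unknown element '%s'", el))
    if (n < 1L) stop(sprintf("invalid count for element '%s'", el))
    total <- total + n * em[[el]]
  }
  total
}

#' Theoretical adduct m/z
#'
#' @param formula Elemental formula of the neutral molecule.
#' @param adduct Adduct name (see [adduct_specs()]) or a one-row adduct
#'   data frame.
#' @return m/z in Da per unit charge.
#' @examples
#' adduct_mz("C10H26N4", "M+Na") # sodiated spermine
#' @export
adduct_mz <- function(formula, adduct = "M+H") {
  spec <- if (is.character(adduct)) adduct_specs(adduct) else adduct
  if (spec$charge == 0) stop("adduct charge must be nonzero")
  (monoisotopic_mass(formula) + spec$delta) / abs(spec$charge)
}

#' Metabolite candidates for a Raman band
#'
#' Returns every library record with a characteristic peak within
#' `tolerance` of the queried shift, sorted by distance to the query and
#' then by name (a deterministic, stable order).
#'
#' @param library A `reference_library`.
#' @param shift Queried Raman shift (cm^-1).
#' @param tolerance Matching window (cm^-1), default 5.
#' @return Data frame with columns `name`, `abbreviation`, `formula`,
#'   `matched_shift`, `delta` (absolute distance); zero rows when nothing
#'   matches.
#' @examples
#' lib <- build_reference_library()
#' match_band(lib, 1571)
#' @export
match_band <- function(library, shift, tolerance = 5) {
  stopifnot(inherits(library, "reference_library"))
  if (!length(library$records)) stop("empty reference library")
  if (tolerance < 0) stop("tolerance must be >= 0")
  rows <- lapply(library$records, function(r) {
    dd <- abs(r$peaks$shift - shift)
    j <- which.min(dd)
    if (dd[j] <= tolerance) {
      data.frame(name = r$name, abbreviation = r$abbreviation,
                 formula = r$formula, matched_shift = r$peaks$shift[j],
                 delta = dd[j], stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(name = character(), abbreviation = character(),
                      formula = character(), matched_shift = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$delta, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Metabolite candidates for an observed m/z
#'
#' Exhaustive search over all (library record, adduct) pairs; pairs whose
#' theoretical adduct m/z lies within `tolerance_ppm` of the observation
#' are returned sorted by absolute ppm error.
#'
#' @param observed Observed m/z (> 0).
#' @param library A `reference_library`.
#' @param adducts Adduct data frame, default `adduct_specs()` positive-mode
#'   triplet `M+H`, `M+Na`, `M+K`.
#' @param tolerance_ppm Matching tolerance in parts per million.
#' @return Data frame with columns `name`, `abbreviation`, `formula`,
#'   `adduct`, `mz`, `ppm_error`.
#' @export
match_mz <- function(observed, library,
                     adducts = adduct_specs(c("M+H", "M+Na", "M+K")),
                     tolerance_ppm = 20) {
  stopifnot(inherits(library, "reference_library"))
  if (observed <= 0) stop("observed m/z must be positive")
  rows <- list()
  for (r in library$records) {
    for (i in seq_len(nrow(adducts))) {
      mz <- adduct_mz(r$formula, adducts[i, , drop = FALSE])
      ppm <- (observed - mz) / mz * 1e6
      if (abs(ppm) <= tolerance_ppm) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = r$name, abbreviation = r$abbreviation,
          formula = r$formula, adduct = adducts$name[i], mz = mz,
          ppm_error = ppm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(name = character(), abbreviation = character(),
               formula = character(), adduct = character(), mz = numeric(),
               ppm_error = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(abs(out$ppm_error), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
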