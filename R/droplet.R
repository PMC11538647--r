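# SlipChip droplet/loading arithmetic. Unit conventions: droplet volumes in
# nL, cell concentrations in cells mL^-1, colloid concentrations in nM.

NL_PER_ML <- 1e6

#' Droplet specification
#'
#' @param volume_nl Droplet volume in nL (> 0).
#' @param cells_per_ml Cell loading concentration in cells mL^-1 (>= 0).
#' @return A list of class `droplet_spec`.
#' @export
droplet_spec <- function(volume_nl, cells_per_ml) {
  if (volume_nl <= 0) stop("droplet volume must be positive")
  if (cells_per_ml < 0) stop("cell concentration must be nonnegative")
  structure(list(volume_nl = volume_nl, cells_per_ml = cells_per_ml),
            class = "droplet_spec")
}

#' Poisson cell-occupancy probabilities of a droplet
#'
#' Cell encapsulation in droplets follows Poisson statistics with mean
#' occupancy `lambda = concentration x volume`. Returns `P(k)` for
#' `k = 0..k_max` plus the tail mass `P(k > k_max)`.
#'
#' @param spec A [droplet_spec()].
#' @param k_max Largest occupancy reported individually (>= 0).
#' @return A list with `lambda`, `k`, `p` (probabilities for `0..k_max`)
#'   and `tail` (`P(k > k_max)`).
#' @examples
#' # 1.5e6 cells/mL in a 1.4 nL droplet: lambda = 2.1
#' poisson_occupancy(droplet_spec(1.4, 1.5e6), k_max = 3)
#' @export
poisson_occupancy <- function(spec, k_max = 4) {
  stopifnot(inherits(spec, "droplet_spec"))
  if (k_max < 0) stop("k_max must be >= 0")
  lambda <- spec$cells_per_ml * spec$volume_nl / NL_PER_ML
  k <- 0:k_max
  p <- stats::dpois(k, lambda)
  list(lambda = lambda, k = k, p = p,
       tail = stats::ppois(k_max, lambda, lower.tail = FALSE))
}

#' Volume of two merged droplets
#'
#' @param v1,v2 Droplet volumes in nL (>= 0).
#' @return Merged volume `v1 + v2` in nL.
#' @examples
#' merge_droplets(1.4, 1.4) # the 2.8 nL lysate droplet
#' @export
merge_droplets <- function(v1, v2) {
  if (v1 < 0 || v2 < 0) stop("volumes must be nonnegative")
  v1 + v2
}

#' Colloid concentration after sedimentation and supernatant removal
#'
#' Assuming complete particle sedimentation, discarding supernatant leaves
#' all particles in the remaining volume.
#'
#' @param c0 Initial concentration (nM).
#' @param v_total Total volume before centrifugation (uL).
#' @param v_discarded Supernatant volume discarded (uL), `< v_total`.
#' @return Final concentration `c0 * v_total / (v_total - v_discarded)` (nM).
#' @examples
#' concentrate_colloid(0.2, 1000, 950) # 4 nM working colloid
#' @export
concentrate_colloid <- function(c0, v_total, v_discarded) {
  if (c0 < 0) stop("concentration must be nonnegative")
  if (v_total <= 0) stop("total volume must be positive")
  if (v_discarded < 0 || v_discarded >= v_total) {
    stop("discarded volume must be in [0, v_total)")
  }
  c0 * v_total / (v_total - v_discarded)
}
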