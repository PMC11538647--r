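---
title: "SERSome simulation and analysis: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SERSome simulation and analysis: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `sersomics`: what the
synthetic-data generator emulates and what it deliberately does not, the
preprocessing algorithms and their numerical choices, how the screening
and clustering stages are configured, and the design decisions taken
where the methodology was genuinely open.

## Why spectral sets

A droplet containing a lysed single cell and silver colloid produces SERS
spectra whose band intensities fluctuate strongly between acquisitions:
nanoparticles and metabolites diffuse, and the number and composition of
plasmonic hotspots sampled by the laser spot changes every time. A single
spectrum is therefore not a reproducible fingerprint. The unit of
analysis in this package is the SERSome — an ordered set of spectra from
one droplet (by default 36, matching a 6 × 6 mapping acquisition) — and
all downstream statistics are ensemble statistics over that set.

## The generator

### Pure-metabolite spectra

Each metabolite in the packaged reference library carries a list of
characteristic peaks (shift, relative amplitude with maximum 1, half
width). A pure spectrum is a sum of Lorentzian lines — the conventional
lineshape for Raman bands — with peak centres quantised to the nearest
grid point, so a line's apex sits exactly on the acquisition grid. The
default grid spans 400–1800 cm⁻¹ at 2 cm⁻¹ spacing (701 points), covering
every band in the library. The default half-width is 8 cm⁻¹.

The library holds 20 metabolites. Peak positions corresponding to
standard band assignments (S–S at 510/542, C–S at 650, adenine ring at
728, C–C at 1077, CH₂ at 1441/1450, COO⁻ at 1560, C–N/C–C at 1571, and so
on) are placed at those literature positions; all remaining positions and
every amplitude and width are synthetic, and the fixture file says so.
Twelve metabolites — spermine, isoleucine, taurine, xanthine, carnosine,
glutamine, adenine, pyridoxine, serotonin, acetylcholine, hypoxanthine
and cystine — carry the 1571 cm⁻¹ band; the other eight do not.

### Fluctuation model

Spectrum *i* of a SERSome is

> xᵢ = Σₘ cₘ · wᵢₘ · pureₘ + baselineᵢ + noiseᵢ

with abundances cₘ from the cell's profile and hotspot weights wᵢₘ drawn
independently per spectrum and metabolite from a mean-1 log-normal with
sigma `fluctuation_sigma` (default 0.22). A multiplicative model reflects
the physics: what varies between acquisitions is how much of each
species sits in enhancing hotspots, which scales its whole peak set. The
baseline is a broad low-order polynomial plus an exponential decay
(quartz/colloid background and residual fluorescence) with per-spectrum
log-normal amplitude jitter (default 0.03); additive white Gaussian noise
has default sigma 0.02 on a peak scale of order 1–10.

The fluctuation and noise defaults were calibrated once so that the
spectral-set stability criterion behaves like a 36-spectrum acquisition:
with the defaults, the mean Pearson correlation between the averages of
two random disjoint 18-spectrum halves is ≈ 0.9992 — above the 0.999
sufficiency threshold with enough margin to be reproducible across
seeds. Because hotspot fluctuation dominates the deficit, the convergence
curve is shallow near its target: it first crosses 0.999 around 28 total
spectra (fixed-seed read-off), and 36 spectra are comfortably sufficient.
A calibration that put the crossing exactly at 36 would require placing a
~1 × 10⁻⁴ PCC difference reproducibly, which seed-to-seed variation does
not permit; we prioritised a robust sufficiency margin.

### Populations

`simulate_population()` draws a young and an aged group. The aged profile
elevates the twelve 1571-carriers (abundance 1 → 1.6) with spermine
raised the most (0.4 → 2.5); all other metabolites are unchanged. Three
sources of cell-to-cell variation are modelled:

- per-metabolite abundance jitter (`cell_sigma`, default 0.1),
- a per-cell global intensity scale (`scale_sigma`, default 0.25) shared
  by all metabolites of the cell — cells differ in size, lysis
  efficiency, and total metabolite release, so absolute brightness varies
  much more than composition,
- a heterogeneity fraction (default 0.1) of young-labelled cells drawn
  from the aged profile, modelling individual cells with an aged-like
  metabolic state inside a nominally young population. Labels keep the
  nominal group; clustering and screening must cope.

The default design is 39 young and 118 aged cells, the sample sizes of a
one-young-line/three-aged-lines fibroblast comparison; tests and the
examples run smaller designs, stated inline, because the statistics of
interest stabilise well below the full design.

What the generator does **not** emulate: electromagnetic hotspot physics
(enhancement factors are folded into the abundance units), wavenumber
miscalibration or drift between spectra, cosmic-ray spikes, detector
saturation, or chemical interactions between metabolites (spectra are
strictly additive). Passing tests on this generator therefore shows the
pipeline recovers planted multiplicative-fluctuation structure; it does
not show robustness to instrument artefacts the model omits.

## Preprocessing

Each spectrum is smoothed with a Savitzky–Golay filter (window 5,
polynomial order 3) and then baseline-corrected with airPLS (difference
order 3, λ = 10⁷, at most 15 iterations, termination ratio 0.001) — in
that order.

**Savitzky–Golay edges.** The `(window−1)/2` points at each end are taken
from the polynomial fitted to the terminal window (the classical edge
treatment, as implemented by `signal::sgolayfilt`). We initially used
mirror padding, but mirroring is not exact for sloped signals: it leaves
an edge artefact that the baseline corrector then rectifies, so
preprocessing was not idempotent on peak-free inputs. The terminal-window
fit reproduces any polynomial up to the filter order over the whole
length, restoring exactness and idempotence.

**airPLS.** The baseline z minimises Σ wᵢ(yᵢ−zᵢ)² + λ‖D³z‖². After each
solve, points at or above the baseline get weight 0 (peaks cannot
attract the baseline) and points below get weight exp(t·|dᵢ|/Σ|d₋|),
with the first and last weight pinned to the maximum so a fully
zero-weighted boundary cannot drift; the exponent is clipped at 50 to
avoid overflow. Iteration stops when the summed negative residual falls
below 0.001 of ‖y‖₁. The reading of "order 3" as the difference-operator
order (not the polynomial order of some basis) is exposed as
`airpls_order` in case a different convention is wanted. The penalized
system is solved sparsely (banded symmetric matrix via the Matrix
package); a test verifies agreement with a dense solve to 1e-8. Because
the termination test is relative, the solver is exactly scale-equivariant.
On smooth backgrounds outside the penalty's polynomial null space (e.g.
exponential decays) the corrected residual is of order 10⁻³ of the input
scale, set by the termination ratio — tighten `airpls_ratio` if that
matters.

No intensity normalization is applied by default at the module level. The
pipeline, however, enables L2 vector normalization after baseline
removal before classification (see below).

## Spectral-set statistics

`pcc_convergence()` draws, for each subset size s, two **disjoint**
s-subsets (overlap would trivially inflate the correlation), averages
each, and records the Pearson correlation; the per-size summary is the
mean over 200 draws with a 5–95 percentile band. `minimum_spectra()`
reads the curve off at a threshold (default 0.999) without interpolating
between listed sizes. The default size ladder for a 36-spectrum set is
s ∈ {2, 4, …, 18}.

## Screening

`rf_screen()` classifies the pooled spectra of all cells — not per-cell
averages, which would discard the fluctuation information — with a random
forest under repeated cross-validation (defaults: 10-fold × 10 repeats in
the module; lighter schemes in the pipeline config, stated there). Three
design decisions matter:

- **Fold unit = cell.** Spectra of one cell are correlated through its
  abundance draw; letting them straddle train/test inflates accuracy.
  Folds are stratified by class over cells.
- **Contribution = impurity importance**, averaged over all fold fits and
  rescaled to sum to 100 %. Shifts with contribution > 0.1 % form the
  selected set.
- **Vector normalization before classification** (pipeline default): with
  a per-cell brightness scale in the data, *every* wavenumber weakly
  separates the groups and importance spreads almost uniformly;
  normalising spectra to unit L2 norm after baseline removal makes
  screening respond to spectral pattern instead of brightness. The
  module-level default leaves normalization off.

Importance at a single grid point is still noisy within one Raman
linewidth — adjacent wavenumbers of a band are nearly perfectly
correlated and share the contribution mass, and a strong neighbouring
band (1560 cm⁻¹) biases narrow summaries. The pipeline therefore reports
the **top band** as the contribution-weighted centroid of the strongest
±12 cm⁻¹ sliding window (`top_contribution_band()`), which recovers the
planted 1571 cm⁻¹ centre to within ~3 cm⁻¹ across seeds, inside the
±5 cm⁻¹ library matching tolerance that determines the candidate list.

Band-pair correlation networks keep edges with ρ strictly above 0.8 and
two-sided p < 0.05 from the t-transform t = ρ√((n−2)/(1−ρ²)) on n−2
degrees of freedom. p-values are not multiplicity-corrected, matching the
conventional printed rule; a Benjamini–Hochberg correction can be applied
to the edge table by the user if wanted. The threshold applies to signed
ρ by default (strong negative co-fluctuations are visible in the matrix
but excluded from the network unless `use_abs = TRUE`).

Group comparisons use the classical two-tailed t-test for two groups
(equal-variance by default, Welch behind a flag) and one-way ANOVA for
more, with the usual star annotation under strict inequalities
(p = 0.05 is "ns").

## Embedding and clustering

Both operate on **relative-intensity** profiles (each cell's or
spectrum's band vector divided by its L1 norm), for the same reason as
normalization before screening: geometry should follow composition, not
brightness — heatmap displays of such data are likewise drawn in relative
intensity. The 2-D embedding is a principal-component projection: exactly
deterministic, duplicate rows map to identical coordinates, and the mean
silhouette width of the nominal labels is reported as the separation
score. Hierarchical clustering uses Ward linkage on Euclidean distances
(`ward.D2`, the variance-minimising Ward criterion on distances);
`stats::hclust` breaks merge ties by lowest index, so row order only
relabels clusters. Dendrograms export to Newick text via `ape`.

## Metabolite matching

Band queries return every library record with a peak within ±5 cm⁻¹
(bands are cited to the nearest cm⁻¹; 5 cm⁻¹ is below the default
linewidth), sorted by distance then name. The adduct m/z calculator uses
monoisotopic element masses and ion-mass adduct constants (Na⁺ as sodium
minus one electron), so displayed 2-decimal values match instrument
printouts; for spermine (C10H26N4) the sodiated adduct computes to
225.20. A 2-decimal observed mass re-queried against the library needs a
tolerance of ~25–30 ppm at m/z 225, since the rounding alone is worth up
to ~22 ppm. The 322.72 silver-cluster background mass is treated as an
instrument background, not a metabolite, and matches nothing at 20 ppm.

## Pipeline reproducibility

`run_pipeline()` derives one seed per stage from the master seed with a
fixed congruential step, so changing one stage's seed does not perturb
the others; artifacts are plain CSV with an md5 manifest, and the report
carries no timestamps, making reruns byte-identical. Stage errors abort
with the stage name; partial artifacts stay on disk.

## Problem sizes

The default interactive configuration runs 12 + 12 cells with 12 spectra
each on the full 2 cm⁻¹ grid; the test suite uses 6–8 cells per group,
3–6 spectra per SERSome and 4–8 cm⁻¹ grids, sizes at which every
statistic under test has already stabilised. The full 39 + 118 design at
36 spectra is a single configuration change.

## Known limitations

- The generator's additivity means spectral unmixing is trivial by
  construction; no claim is made about deconvolving real overlapping
  metabolite signatures.
- The minimum-spectra read-off depends on the calibrated fluctuation
  level; on real instruments it must be re-measured per substrate and
  protocol.
- Correlation networks inherit the usual caveat that band correlations
  mix chemical co-occurrence with shared hotspot physics; the package
  computes the networks and leaves pathway interpretation to the user.
- The m/z matcher handles the four common adducts of singly charged small
  molecules; it does not model isotope patterns or in-source fragments.
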