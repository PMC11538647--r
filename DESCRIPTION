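Package: sersomics
Title: Single-Cell Metabolic Profiling from Fluctuating SERS Spectral Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of SERSomes: sets of fluctuating
    surface-enhanced Raman spectra collected from single-cell nanoliter
    droplets. Provides a synthetic-data generator for hotspot-driven
    spectral fluctuation over a reference metabolite peak library,
    Savitzky-Golay smoothing and adaptive iteratively reweighted penalized
    least squares (airPLS) baseline correction, Pearson-correlation
    spectral-set convergence statistics, random-forest screening of
    discriminative Raman shifts with grouped cross-validation, correlation
    networks of band intensities, embedding and hierarchical clustering of
    feature profiles, and matching of candidate bands to metabolites by
    characteristic Raman peaks and theoretical adduct masses. Includes
    droplet-loading (Poisson occupancy) and colloid-preparation arithmetic
    for the underlying microfluidic protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    grDevices,
    signal,
    ranger,
    cluster,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
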