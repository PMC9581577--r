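Package: spheromea
Title: Analysis of Neuronal Spheroid-Network Activity on Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of extracellular recordings from human
    iPSC-derived neuronal cultures on 60-channel microelectrode arrays,
    together with quantification of spheroid (cell-cluster) morphology from
    phase-contrast images. Provides band-pass filtering and double-sided
    threshold spike detection, PCA plus scanning k-means spike sorting with
    automatic unit-count ("knee") estimation, adaptive log-ISI burst
    detection, network-burst detection from burst co-occurrence, per-unit
    activity metrics (burstiness, network burstiness, log-ISI entropy,
    instantaneous-rate correlation), bootstrap confidence intervals and
    stratified morphology-activity comparisons, an HDF5 recording container,
    and seeded synthetic-data generators for recordings and images so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    rhdf5,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
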