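Package: msikit
Title: Mass Spectrometry Imaging Toolkit for Spatial Lipidomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted analysis of centroided mass spectrometry
    imaging (MSI) data in lipidomics studies of neurodegenerative disease
    models. Provides exact monoisotopic mass and adduct m/z computation,
    isotope-envelope simulation, reading and writing of processed imzML,
    ppm-windowed ion-image extraction with adduct summing and colocalization
    scoring, quadrant region-of-interest z-score statistics under three
    normalization schemes, volcano-style differential abundance analysis with
    Benjamini-Hochberg correction, parallel-reaction-monitoring breakdown
    curves with collision-energy optimization, two-solvent detection
    comparisons, and a seeded synthetic sagittal-brain phantom generator with
    known ground truth so every stage of the pipeline can be validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    xml2,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
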