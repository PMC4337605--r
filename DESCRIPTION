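Package: afmhelix
Title: Helical Pitch, Cluster Growth and Severing Analysis for High-Speed
    AFM Movies of Actin Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify conformational changes of actin filaments in
    time-lapse high-speed atomic force microscopy (HS-AFM) height maps.
    Implements spike-noise removal and plane flattening, filament backbone
    tracing, semi-automatic crossover-peak detection with center-of-mass
    refinement, half-helical pitch and peak-height statistics with
    paracrystal-calibrated measurement-error decomposition, classification
    of cofilin-decorated half helices, cluster delimitation with
    neighbor-pitch asymmetry tables, directional growth-event counting,
    and detection plus four-way classification of filament severing sites.
    A synthetic movie generator renders parametric filament models with a
    periodic crossover envelope, spherical-tip dilation and calibrated
    localization error, so that every analysis stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
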