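Package: mtflare
Title: Quantification of Microtubule End Shapes, Protofilament Clustering,
    and Tip-Proximal Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the three-dimensional shapes of
    protofilaments at microtubule plus-ends traced from electron
    tomograms, and for the TIRF-microscopy readouts that accompany such
    experiments. Provides cylinder-axis fitting, bend segmentation of
    protofilament flares, a weighted lateral-overlap statistic with
    threshold sweeps and connected-component clustering, lattice-spacing
    estimation by autocorrelation, decoration-thickness measurement,
    envelope-boundary detection by change-point fitting, envelope
    intensity ratios, FRAP recovery fitting, single-molecule dwell-time
    analysis with censoring, constrained stoichiometry mixtures, and the
    condition-comparison statistics used throughout (chi-squared,
    Welch's t, Kolmogorov-Smirnov, two-way ANOVA). A synthetic-data
    generator emulates every input class with known ground truth so that
    all stages are testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
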