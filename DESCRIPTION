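Package: timerflow
Title: Preprocessing of Fluorescent Timer Flow-Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for preprocessing single-cell flow-cytometry measurements
    of Fluorescent Timer proteins, whose chromophore matures irreversibly
    from a blue-emitting immature form to a red-emitting mature form.
    Provides negative-control-based thresholding of Timer positivity,
    log-domain normalization of blue and red fluorescence against
    autofluorescence statistics, and the trigonometric transformation of
    normalized fluorescence into Timer Angle (degrees, 0 = new expression,
    90 = aged expression) and Timer Intensity. Includes a kinetic simulator
    of blue-to-red chromophore maturation for generating fully synthetic
    time-course datasets, batch processing over sample manifests, quality
    control summaries and plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
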