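Package: phaseport
Title: Phase-Portrait Staging of Thermoresponsive Polymer Phase Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the number and character of phase-transition
    stages in solutions and gels of thermoresponsive polymers from turbidimetry
    curves and differential scanning calorimetry (DSC) thermograms. Implements
    direct phase portraits (numerical differentiation of optical-density
    curves), inverse phase portraits (numerical integration of heat-flow
    curves), segmentation of portraits into parabolic, linear and intermediate
    fragments with a stage-counting rule, analytic single-stage models
    (logistic sigmoid and exponential saturation) and their exact portraits,
    and a division-based decomposition of two-stage transitions into the
    product of the two stage models. Includes a seeded generator of synthetic
    turbidity curves and thermograms for validation and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
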