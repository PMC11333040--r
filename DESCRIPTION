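Package: dynonset
Title: Decoupling the Protein Dynamical Transition from Hydration-Water
    Onsets in Elastic Neutron Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and analysis of elastic fixed-window
    neutron scattering scans and DSC thermograms for separating an
    intrinsic, hydration-dependent protein dynamical transition from a
    purely resolution-limited apparent onset in hydration-water dynamics.
    Provides normalization to the low-temperature baseline, q-summation,
    Gaussian-approximation mean-squared-displacement extraction,
    segmented-regression and threshold onset detection with bootstrap
    uncertainty, Arrhenius activation-energy fitting with
    resolution-window crossing temperatures, glass-transition midpoint
    extraction from DSC curves, and an orchestrated study pipeline that
    renders a decoupling verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
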