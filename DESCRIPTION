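Package: astromap
Title: Astrocyte-Gated Self-Organizing Orientation Maps in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the development of orientation preference maps in
    primary visual cortex with a gain-controlled, homeostatically adaptive,
    laterally connected (GCAL/LISSOM-family) rate model augmented by an
    astrocyte layer. Astrocytes pool local synaptic drive over a
    configurable anatomical radius and set the sliding threshold of a
    BCM-type plasticity rule for lateral excitatory connections, so that
    the astrocyte radius controls the width of orientation hypercolumns;
    small radii yield salt-and-pepper maps. Includes a full map-analysis
    suite: Fermi-filtered difference maps, radially averaged power spectra
    with Gaussian-peak fits of the column spacing, subpixel pinwheel
    detection with topological charge, pinwheel density per hypercolumn,
    stability indices between maps, and local orientation similarity
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
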