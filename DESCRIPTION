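Package: spiraltomo
Title: Spiral Bright-Field Tomography for Light Sheet Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free optical projection tomography in a selective plane
    illumination microscopy (SPIM) geometry. Simulates spiral bright-field
    acquisitions of translucent specimens (defocus-blurred Beer-Lambert
    transmission of ellipsoid/sphere phantoms), fuses per-angle through-focus
    stacks into extended-depth-of-field projections, reconstructs isotropic
    attenuation volumes by filtered back-projection with automatic
    variance-based rotation-axis finding, and registers fluorescence SPIM
    stacks, spherical landmarks and time-lapse volumes onto the tomographic
    reference frame.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
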