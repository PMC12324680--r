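Package: helmcoil
Title: Helmholtz Coil Exposure-System Design and Cytoskeletal Fiber
    Alignment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design computations for water-cooled Helmholtz coil pairs used
    in weak-magnetic-field cell biology experiments: off-axis magnetic field
    of circular loops via complete elliptic integrals, discretization of
    multilayer windings into filamentary loops, field maps and homogeneity
    reports over a culture-dish region, Helmholtz spacing optimization, RL
    step response and switching-frequency limits, impedance matching,
    resistive heat dissipation into cooling water, and dew-point
    condensation-safety analysis for incubator operation. Also implements a
    structure-tensor readout of cytoskeletal fiber alignment in grayscale
    micrographs (a 0-100 percent coherency-based score), rank-based group
    comparison, fluorescence-ratio error propagation, and a seeded synthetic
    fiber-image generator with axial von Mises orientations for end-to-end
    testing of the image pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    png,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
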