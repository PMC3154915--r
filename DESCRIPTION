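Package: granulegold
Title: Secretory-Granule Bioenergetics and Quantitative Immunogold Stereology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying glutamate handling by endocrine secretory
    granules. One arm integrates a thermodynamically consistent flux model of
    the granule membrane (vacuolar H+-ATPase, vesicular glutamate transporter,
    and an EAAT2-class coupled glutamate carrier, plus optional Cl- and leak
    conductances) to predict the granule membrane potential, luminal pH and
    luminal glutamate under different transporter complements. The other arm
    generates synthetic ultrathin-section geometries with compartment-wise
    Poisson immunogold labelling and runs the matching quantification
    pipeline: 30-nm membrane/vesicle assignment, grid-point stereological
    areas, background-corrected particle densities, ratio statistics with
    Mann-Whitney U tests, and density-to-concentration calibration against
    test sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
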