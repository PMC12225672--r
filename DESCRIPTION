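Package: subcellsugars
Title: Subcellular Sugar Compartmentation, Volumetrics and Invertase Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline from raw leaf measurements to subcellular
    sugar concentrations and invertase flux estimates. Computes the
    electrolyte-leakage index of injury, deconvolves non-aqueous
    fractionation (NAF) density-gradient profiles into plastidial,
    cytosolic and vacuolar metabolite shares via simplex-constrained
    least squares against marker-enzyme profiles, converts leaf
    morphometry and 3D segmentation summaries into absolute compartment
    volumes per gram dry weight, combines bulk metabolite amounts with
    shares and volumes into millimolar compartment concentrations, and
    simulates Michaelis-Menten sucrose cleavage with competitive
    (fructose) and noncompetitive (glucose) inhibition after Arrhenius
    temperature adjustment of measured enzyme activities. A seeded
    synthetic-data generator with retrievable ground truth makes every
    stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
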