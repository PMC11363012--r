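Package: scmsquant
Title: Quantitative Single-Cell Mass Spectrometry of Plant Natural Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for plate-based single-cell mass spectrometry
    (scMS) of plant protoplasts: accurate-mass molecular formula and adduct
    annotation with a ppm tolerance and RDBE filtering, external calibration
    with back-calculation-based linear-range and LOQ determination, conversion
    of peak areas to absolute in-cell molar concentrations using spherical
    cell volumes estimated from imaged diameters, marker-metabolite cell-type
    annotation, and population partitioning by hierarchical and k-means
    clustering. Includes a synthetic protoplast-population generator that
    emulates the cell-type structure of Catharanthus roseus leaf, root, and
    petal tissues so that every stage of the pipeline can be verified against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
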