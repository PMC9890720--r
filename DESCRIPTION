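Package: immunotopo
Title: Tumour-Immune Topography Analysis of IHC Tissue Microarray Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tumour-immune topography in
    brightfield immunohistochemistry (IHC) images of tissue microarray
    (TMA) cores. Separates haematoxylin and DAB staining by colour
    deconvolution in optical-density space, detects marker-positive
    immune cells, classifies pixels into tumour and stroma compartments
    with a random-forest pixel classifier, and derives per-compartment
    cell densities, hot/cold/excluded tumour-immune phenotypes,
    PD-L1 combined positive scores, and the associated contingency-table
    and Kaplan-Meier statistics. Includes a seeded synthetic TMA cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    survival,
    yaml,
    jsonlite,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
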