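Package: vuvcd
Title: Secondary-Structure Inference from Vacuum-UV Circular Dichroism Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring protein secondary structure from (vacuum-UV)
    circular dichroism spectra: unit handling and normalization of CD spectra
    to molar circular dichroism, a self-consistent SVD (SELCON3-style)
    deconvolution of a query spectrum into six secondary-structure fraction
    classes against a reference database, estimation of alpha-helix and
    beta-strand segment numbers from distorted-structure fractions,
    content- and segment-constrained per-residue secondary-structure
    assignment from propensity scores, and comparison of assignments (for
    example hydrogenated versus perdeuterated forms of the same protein).
    Includes a synthetic-data generator (Gaussian-band basis spectra,
    reference sets, planted-truth propensity profiles) so the whole pipeline
    is testable without access to a measured reference database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
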