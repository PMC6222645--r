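Package: quechersrsm
Title: Response-Surface Optimization of QuEChERS Extraction for
    Cyclohexanedione Herbicide Residues in Soil
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric workflow for optimizing QuEChERS ("quick, easy,
    cheap, effective, rugged, and safe") extraction of cyclohexanedione
    oxime herbicide residues from soil. Builds face-centred central
    composite designs over five extraction variables, fits 31-term
    polynomial recovery models (linear, two-way, three-way and quadratic
    terms in the coded factors) by ordinary least squares with
    confidence-level significance letters, audits significance-based term
    removal against the resulting prediction deviations, searches the
    design region for extraction conditions driving all compounds'
    predicted recoveries to a target with a minimum-variable tie-break,
    and quantifies LC-MS matrix effects from paired solvent/matrix
    calibration slopes. Includes a synthetic-data generator so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
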