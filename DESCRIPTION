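Package: hiophase
Title: Iterative Transform Phase Improvement for Macromolecular Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves crystallographic phases by iterative transform density
    modification: hybrid input-output (HIO) negative feedback in the solvent
    region, a dynamically evolving protein mask delineated from a
    Gaussian-weighted average of the electron density, and histogram matching
    inside the mask. Starting phases may come from a placed template model
    (molecular replacement) or from random phases for high-solvent-content
    crystals. Includes a synthetic toy-crystal generator so the full method is
    testable without external data, SF-mmCIF and CCP4/MRC input/output, and
    monitoring statistics (amplitude-weighted mean phase error, free R,
    convergence detection).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
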