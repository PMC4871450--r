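Package: statomorph
Title: Statolith Outline Morphometrics and Taxon Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outline-based geometric morphometrics for cubozoan statoliths
    and similar hard parts. Reads binary silhouette images of the proximal,
    oral and lateral statolith faces, extracts closed outlines, computes
    traditional length-to-width ratios and elliptical Fourier descriptors
    with first-harmonic normalisation, and discriminates species and
    families by canonical discriminant analysis with Wilks' lambda, Rao's F
    approximation and leave-one-out jackknifed classification. Includes a
    synthetic silhouette generator with nested family/species structure so
    the whole pipeline can be exercised and validated without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
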