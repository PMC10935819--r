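Package: chemseg
Title: Chemical Structure Segmentation from Document Pages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and extracts individual molecular-structure depictions
    from document page images. Provides a synthetic page/mask generator that
    renders molecules from SMILES onto document-like pages, an
    adapter-augmented vision-transformer segmentation model with a promptable
    mask decoder, a deterministic pixel-level mask refinement stage
    (mean-threshold binarization, Hough line removal, scaled square dilation,
    connected-component mask update, small-region filtering, cropping), a
    heuristic false-positive filter, and an end-to-end document pipeline with
    completeness/redundancy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rsvg,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on the PATH) for SMILES depiction
Config/testthat/edition: 3
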