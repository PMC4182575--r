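Package: hcscreen
Title: Image-Based Arrayed shRNA Screen Simulation, Quantification and Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based loss-of-function antiviral screens in
    arrayed (96-well) format: a synthetic two-channel microscopy generator
    with ground truth (Hoechst nuclei plus a GFP infection reporter under a
    single-hit Poisson dose model), nuclei segmentation and GFP-positive
    cell classification, per-well infection efficiency, per-plate range
    normalization against in-plate control medians, pooled Z scores against
    the irrelevant-shRNA null, shRNA- and gene-level hit calling with
    cytotoxicity and expression exclusions, a fast well-level screen
    simulator for power and false-positive studies, and small utilities for
    follow-up assays (2^-ddCt relative expression, knockdown-phenotype
    rank correlation, viability-normalized reporter activity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    withr,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
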