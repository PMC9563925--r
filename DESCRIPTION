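Package: rarebiopsy
Title: Unbiased Rare-Event Detection, Classification and Enumeration for
    Liquid-Biopsy Immunofluorescence Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end analysis pipeline for enrichment-free liquid-biopsy
    slide imaging. Detects rare events (circulating tumor cells and oncosomes)
    in dense leukocyte monolayers imaged in four fluorescence channels,
    extracts morphometric features, separates rare from common events by
    principal-component reduction and hierarchical clustering, assigns
    channel-type classifications and CTC subtypes, converts counts to events
    per millilitre of blood, harmonizes two staining protocols for multi-assay
    morphometric clustering with silhouette-based model selection, and relates
    enumerations to progression-free survival. Includes a synthetic slide and
    cohort generator with full ground truth so every stage is testable without
    scanned slides.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    cluster,
    survival,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
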