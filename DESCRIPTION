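Package: histoquant
Title: Quantification of Amyloid, Vascular and Astroglial Pathology in
    Fluorescence Histology Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a fluorescence-histology
    quantification workflow for mouse models of cerebral amyloidosis:
    per-channel segmentation (global histogram thresholds and Bernsen
    auto-local thresholding), region-of-interest area fractions and
    mask-algebra colocalization metrics (vascular and plaque-associated
    GFAP, vascular and parenchymal ICAM-1), morphological separation of
    cerebral amyloid angiopathy (CAA) from parenchymal plaques, vessel
    skeleton morphometry (diameter and tortuosity), and the factorial
    statistics stage (two-way Type III ANOVA with Sidak-adjusted
    pairwise comparisons, unpaired t and exact Mann-Whitney tests).
    Includes a synthetic histology generator with exported ground truth
    so every stage is validated end to end without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
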