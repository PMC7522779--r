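Package: pexphos
Title: Single-Cell Fluorescence Quantification and Phosphoproteomics
    Bookkeeping for Peroxisomal Protein Import Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cytosolic GFP fluorescence of single yeast
    cells from paired bright-field and GFP z-stacks (bright-field
    segmentation, maximum-intensity projection, quantile-based cytosolic
    intensity with background correction and per-strain centering, and
    Welch comparisons between strains), together with an in-silico
    phosphoproteomics engine (multi-protease digestion with missed
    cleavages, phosphopeptide monoisotopic masses and m/z, multistage
    activation neutral-loss offsets, and confidence-filtered
    phosphosite-table assembly) and iBAQ-based complex-composition
    normalization. Synthetic generators produce ground-truthed microscopy
    stacks and evidence/iBAQ tables so every stage of the pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
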