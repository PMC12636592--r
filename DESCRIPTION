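Package: issq
Title: Stitching, Alignment and Read Calling for In Situ Sequencing Image Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing multi-cycle in situ sequencing microscopy
    experiments. Tile sets from all imaging cycles are registered jointly on a
    pairwise-constraint graph: overlapping pairs are refined by phase
    cross-correlation, scored by zero-normalized cross-correlation, filtered
    against a null of non-overlapping pairs, repaired from a robust linear
    stage model, and solved globally by weighted least-absolute-error
    regression (with least-squares and spanning-tree alternatives), then
    integerized and merged into aligned per-cycle mosaics. From the aligned
    stack, amplicon colonies are detected with a difference-of-Gaussian and
    Laplacian-of-Gaussian filter cascade, bases are called per cycle, reads
    are assigned to cells and matched to a barcode library by edit distance.
    A synthetic scene generator with exact ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quantreg,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
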