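Package: cycloess
Title: Cyclic Loess Normalisation of Heterogeneous Common-Reference
    Two-Colour Microarray Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Normalises heterogeneous two-colour common-reference cDNA
    microarray datasets in a single run.  Unprocessed GenePix (GPR/ATF)
    and BlueFuse image-analysis files, in any mixture and with any number
    of distinct array layouts, are parsed without gene-array-layout
    (.gal) files.  Within-array preprocessing (background correction,
    spot filtering, automatic reference-channel detection for dye swaps,
    block-by-block median centering, duplicate averaging) is followed by
    all-pairs cyclic loess normalisation on MA-plots, antisymmetric
    averaging of the pairwise normalised log2-ratios with explicit
    missing-value bookkeeping, and a final per-array median correction.
    Includes diagnostic boxplot/MA-plot summaries, a ground-truth
    simulator for two-colour common-reference data, and a simple
    differential-expression evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, tools
Suggests: testthat (>= 3.0.0), limma, optparse, jsonlite
Config/testthat/edition: 3
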