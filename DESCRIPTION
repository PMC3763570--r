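Package: PSPCPloc
Title: Submitochondrial Protein Localization from Positional Specific
    Physicochemical Properties
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the submitochondrial location (inner membrane, matrix,
    outer membrane) of mitochondrial proteins from sequence alone.  Protein
    sequences are represented by positional specific physicochemical
    properties (PSPCP): the expectation of z-scored amino-acid property
    scales under the per-position substitution distribution obtained by
    softmax standardization of a PSI-BLAST position-specific scoring matrix.
    PSPCP series are embedded in the amphiphilic pseudo-amino-acid
    composition framework, yielding a compact 20 + lambda*R descriptor per
    protein, and classified with a one-vs-one RBF-kernel support vector
    machine.  Includes jackknife and repeated hold-out evaluation with
    per-class accuracy and Matthews correlation coefficients, grid
    calibration of the descriptor and kernel parameters, a synthetic
    sequence/PSSM generator for end-to-end testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
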