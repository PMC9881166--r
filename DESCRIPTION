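Package: radkit
Title: Angular Decomposition of Ribosomal Subunit Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies the orientation of the ribosomal small-subunit body
    and head as three Euler-style angles (rotation, tilt, tilt direction)
    plus a rotation center and residual translation, measured against fixed
    reference frames derived from classical and rotated reference
    structures. Provides rigid-body superposition and screw-axis geometry,
    rRNA core identification by global sequence alignment and iterative
    spatial pruning, pairwise orientation comparison (Euler-Rodrigues angle
    and tilt difference), smFRET probe-distance analysis, and a seeded
    synthetic pseudo-ribosome generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
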