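Package: qrotate
Title: Q-Methodology Factor Extraction, Orthomax Rotation, and
    Rotation-Impact Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: By-person factor analysis for Q-methodology: Pearson
    correlation of Q-sorts, factor extraction by principal components or
    iterated principal-axis factoring, the orthomax family of orthogonal
    rotations (Quartimax, Varimax, Equamax) via pairwise Jacobi sweeps,
    Q-sort flagging, factor z-scores and integer factor arrays,
    distinguishing-statement detection, and a rotation-impact comparison
    procedure that matches rotated factors to unrotated ones by maximum
    absolute correlation of factor scores and accounts for changed
    distinguishing statements. Includes a forced-distribution synthetic
    Q-sort generator with known latent viewpoint structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
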