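Package: halfsam
Title: Half-SAM Scores for Differential Expression in Heterogeneous Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moderated two-sample scores for calling differentially expressed
    genes when the case group is heterogeneous. Implements the half-SAM score,
    whose denominator uses only the control-group standard deviation plus a
    fudge factor, together with its comparators (pooled Student's t, half
    Student's t, and the SAM score), fudge-factor estimation by
    coefficient-of-variation minimisation, permutation-based inference with
    per-gene and pooled null conventions, Benjamini-Hochberg FDR control, a
    Monte Carlo engine for type-I-error and power studies under normal,
    uniform, skewed-gamma and mixture expression models, tab-delimited
    expression-matrix input (including the Alon colon-cancer label dialect),
    and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
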