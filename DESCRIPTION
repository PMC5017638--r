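Package: netstim
Title: Stimulation and Control of Nonlinear Brain Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates networks of delay-coupled, noisy Wilson-Cowan neural
    mass oscillators on weighted structural connectomes, applies focal
    stimulation to single regions, and relates the functional and structural
    consequences of stimulation to linear network-control diagnostics
    (average and modal controllability, steady-state response). Includes a
    synthetic-connectome generator with modular block structure and spatial
    embedding, lagged cross-correlation functional connectivity, oscillatory
    transition sweeps, and ANOVA-based intraclass correlation for
    reproducibility analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
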