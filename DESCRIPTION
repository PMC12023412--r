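Package: mbcorrect
Title: Mass-Balance Correction for Protein Stability Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrofits potential-like protein stability (ddG) predictors with
    an additive mass-balance correction that models the neglected
    unfolded-state free-energy difference as per-residue contributions of the
    two amino acids swapped by a single-point mutation. Provides the
    occurrence encoding of mutations, ridge fitting of the data-driven
    correction (20 residue coefficients plus a score weight), a two-parameter
    variant based on the Rose mean-area-buried scale, structurally
    antisymmetric prediction, evaluation metrics (Pearson correlation, RMSE,
    direct/inverse antisymmetry diagnostics), dataset merging with precedence
    and antisymmetric augmentation, a synthetic benchmark generator with
    planted coefficients, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
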