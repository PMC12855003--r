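Package: scouter
Title: Predicting Transcriptional Responses to Unseen Genetic Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts genome-wide transcriptional responses to unseen single-
    and two-gene perturbations from Perturb-seq-style expression data. A
    compressor network condenses a control cell's expression profile into a
    low-dimensional state, which is concatenated with a frozen text-derived
    gene embedding of the perturbation and decoded by a generator network into
    the predicted perturbed profile. Training pairs each perturbed cell with a
    randomly drawn control cell and minimises an autofocus direction-aware
    loss. Includes perturbation-level data splitting, top differentially
    expressed gene evaluation metrics with bootstrap confidence intervals, and
    a synthetic Perturb-seq simulator with embedding-linked ground-truth
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
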