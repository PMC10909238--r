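Package: dtocrop
Title: Metaheuristic-Tuned Extreme Learning Machines for Crop Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Crop classification from labeled remote-sensing image patches using an
    extreme learning machine (ELM) whose surrounding pipeline is tuned by swarm
    metaheuristics: dipper-throated optimization (DTO) selects feature-extractor
    hyperparameters and a modified sine-cosine algorithm (MSCA, a sine-cosine /
    firefly hybrid) tunes the ELM itself. Includes a synthetic drone-style crop
    patch generator, a pluggable feature-extractor registry with a deterministic
    convolutional filter bank, per-class one-vs-rest evaluation reports (accuracy,
    precision, recall, F-score, MCC) with macro averages, and an end-to-end
    reproducible pipeline with stratified splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
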