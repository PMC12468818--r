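Package: painvoice
Title: Speech-Based Pain Classification with Bidirectional GRUs on Log-Mel Spectrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting pain and grading its intensity from short
    speech recordings. Audio clips are standardized to a fixed-rate,
    fixed-length waveform, converted to Log-Mel spectrograms, and classified
    with a stacked bidirectional gated recurrent unit (GRU) network whose
    per-frame outputs are mean-pooled over time into an utterance embedding.
    Training uses class-balanced cross-entropy, Adam with L2 weight decay,
    early stopping, and speaker-independent train/test splits. Includes a
    synthetic vocalization corpus generator with controllable fundamental
    frequency, energy, and jitter effects so the full pipeline can be
    exercised and validated without clinical audio, plus confusion-matrix
    based evaluation reports and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
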