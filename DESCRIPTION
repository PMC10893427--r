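Package: maglink
Title: Macro-Activity Recognition by Graph Link Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and validates composite human macro-activities (multi-step
    exercises, recipes) in streams of micro-activity embeddings from wearable
    sensors. Micro-activity sequences are encoded as directed star graphs with
    sinusoidal positional encodings and processed by a small multi-task graph
    attention network with two binary heads: a graph validator that decides
    whether the current sequence is a complete macro-activity, and a link
    predictor that decides whether the next micro-activity can extend it. The
    package includes an exact grammar oracle over valid activity sequences, a
    class-conditional Gaussian generator for fully synthetic training data, a
    streaming state machine that segments continuous micro-activity streams,
    and an evaluation grid over embedding dimension, noise level and
    positional-encoding ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
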