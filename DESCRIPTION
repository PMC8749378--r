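Package: pgsom
Title: Pruning Growing Self-Organizing Maps for Wearable-Sensor Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Unsupervised classification of human physical activity from
    wearable accelerometer and ventilation sensors with a dynamically
    growing and pruning self-organizing map (PGSOM). The map starts from
    four neurons on an unbounded two-dimensional lattice, grows new
    neurons at boundary winners whose cumulative quantization error
    exceeds a spread-factor threshold, and deletes neurons whose age
    (presentations since last activation) exceeds an age threshold.
    Includes fixed-topology SOM and growing-only GSOM modes, neuron
    calibration from a small labeled subset, a 101-dimensional
    time-series feature pipeline for 30 Hz sensor logs, a synthetic-data
    generator with class imbalance and an overlapping class pair,
    evaluation and cross-validation machinery (accuracy, Cohen's kappa,
    macro F-measure), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
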