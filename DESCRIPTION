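Package: msdcnn
Title: Minimum-Signed-Digit Weight Approximation for Fixed-Point CNN Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-training approximation of convolutional neural network
    weights in the minimum-signed-digit (MSD) number system, for hardware
    that multiplies by shift-and-add instead of full combinational
    multipliers. Provides canonical non-adjacent-form recoding, truncation
    to a budget of p nonzero digits, a compact 16-bit packed weight layout,
    Q(m, n) fixed-point quantization, a bit-exact software model of a
    saturating shift-and-add multiply-accumulate unit, exhaustive error
    analysis (normalized mean error distance and nonzero-digit statistics),
    a fixed-point inference simulator for small CNNs, and seeded synthetic
    image-classification fixtures so the accuracy/efficiency trade-off can
    be studied without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
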