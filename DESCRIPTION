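Package: qpralign
Title: Quantum Pattern Recognition Dot-Plot Alignment by Simulated QFT and Laue Peak Indexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pairwise sequence alignment by diagonal pattern detection in
    dot-plot windows. A binary dot matrix is fragmented into power-of-two
    window spaces; a statevector simulation of a quantum pattern recognition
    routine (uniform superposition, oracle flagging of matching cells, flag
    measurement, quantum Fourier transform, wave-number sampling) detects
    periodic line patterns, and Laue-equation peak indexing infers each
    line's length, angle and position. Detections become anchor records that
    are validated against the sequences and refined by Needleman-Wunsch or
    Smith-Waterman dynamic programming. Includes a synthetic-data generator
    for planted homologies and planted line patterns, a classical diagonal
    scanning analogue with precision/recall evaluation, a quantum gate
    resource estimator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
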