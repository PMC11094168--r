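Package: poremod
Title: Multi-Type RNA Modification Detection from Nanopore Direct RNA
    Sequencing Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects RNA modifications (m6A, m5C, pseudouridine and
    others) from nanopore direct RNA sequencing signal. Takes per-read,
    per-base resquiggled current events, normalizes and resamples them
    into fixed-size 5-mer instances, and classifies each read with a
    two-branch neural network (1D convolutions, bidirectional LSTMs and
    an attention unit over the current signal; a bidirectional LSTM over
    base-level statistics). Supports de novo training, transfer learning
    to new modification types by freezing the feature extractor,
    read-level probability filtering, site-level calling with
    false-positive control, stoichiometry estimation, and differential
    modification testing between conditions via Fisher's exact test. A
    seeded squiggle simulator with known ground truth makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
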