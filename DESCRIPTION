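Package: vowelage
Title: Vowel-Partitioned Age Estimation from Children's Speech with Fuzzy Decision Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates a child speaker's age (7-12 years) from sustained vowel
    recordings. Implements a narrow Mel-filterbank cepstral front end (40 static +
    40 delta + 40 delta-delta coefficients), per-vowel single-hidden-layer networks
    trained by the extreme learning machine and its self-adaptive variant
    (differential-evolution search over input weights with an analytic output
    solve), a linear maximum-margin vowel gate for routing unlabeled utterances,
    and a fuzzy-or fusion of the per-vowel decisions weighted by local (score-gap)
    and global (leave-one-out recall) confidence. Includes a synthetic sustained
    vowel corpus generator with age-dependent pitch and formant scaling, a 3-fold
    speaker-disjoint cross-validation harness with confusion-matrix reporting and
    age-group collapsing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
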