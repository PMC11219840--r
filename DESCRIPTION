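Package: dnmspop
Title: Synthetic Delayed Non-Match-to-Sample Sessions and Calibrated
    Population Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates stage-structured whisker delayed non-match-to-sample
    (DNMS) go/no-go sessions with planted neural, cholinergic and behavioral
    effects, and implements the analysis chain used to characterise them:
    calcium event estimation by AR(1) constrained deconvolution (OASIS-style
    pool adjacent violators) with shot-noise normalisation, a linear
    max-margin population-decoding suite with label-shuffle and
    weight-shuffle null calibration (session, cross-temporal, cross-session
    and cross-condition decoders, decodable-onset statistic,
    decision-variable projection), a choice-selectivity index, a small
    noisy-ReLU autoencoder familiarity model trained with ADAM, an
    L1-penalised Normal GLM of bulk acetylcholine signals with
    delta-AIC task-factor importance, and the d-prime based adaptive
    training rules that drive stage advancement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
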