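Package: fluidvote
Title: Network-Based Prediction of the Body Fluids Receiving Secreted Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts which human body fluids a secreted protein is likely to
    be secreted into from a weighted protein-protein interaction (PPI)
    network, by a one-hop weighted vote over annotated interaction partners.
    Each candidate fluid is scored as the sum of interaction confidences to
    neighbours known to occur in that fluid, and the eleven canonical fluids
    (amniotic fluid through urine) are returned in descending score order.
    Includes the full ranked multi-label evaluation framework (leave-one-out
    order accuracies, average label count, random-guess baseline, top-k
    coverage likelihood), readers and writers for STRING-style edge lists and
    fluid annotation tables, a synthetic benchmark generator with plantable
    label homophily, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
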