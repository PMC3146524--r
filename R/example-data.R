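#' Packaged worked example: peptidoglycan recognition protein 1
#'
#' The interaction neighbourhood of human peptidoglycan recognition protein 1
#' (UniProt O75594), a secreted protein detected in plasma/serum, saliva and
#' urine: its 23 weighted interactions with annotated secreted proteins,
#' shipped as plain TSV fixtures. Scoring O75594 on this star network ranks
#' plasma/serum, saliva and urine as the first three orders — the protein's
#' actual fluids — which is the canonical sanity check for the weighted-vote
#' method.
#'
#' @return A list with `network` (a [ppi_network()], 24 proteins / 23
#'   edges), `annotations` (a [fluid_annotations()], 24 proteins) and
#'   `vocab` ([body_fluids()]).
#' @export
#' @examples
#' ex <- pgrp1_example()
#' fit <- fluidvote(ex$network, ex$annotations)
#' predict(fit, "O75594", top_k = 3)
pgrp1_example <- function() {
  net <- read_network(system.file("extdata", "pgrp1_network.tsv",
                                  package = "fluidvote", mustWork = TRUE))
  ann <- read_annotations(system.file("extdata", "pgrp1_annotations.tsv",
                                      package = "fluidvote", mustWork = TRUE))
  list(network = net, annotations = ann, vocab = attr(ann, "vocab"))
}
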