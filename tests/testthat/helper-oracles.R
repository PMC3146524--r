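# Independent brute-force oracles and raw random-instance builders. These
# deliberately avoid the package's vectorized scoring path and its synthetic
# generator, so they can serve as cross-checks for both.

# Naive per-edge accumulation of the weighted neighbour vote.
oracle_score <- function(q, net, ann, vocab, exclude = NULL) {
  s <- stats::setNames(numeric(nrow(vocab)), vocab$type)
  e <- net$edges
  for (r in seq_len(nrow(e))) {
    nb <- if (e$a[r] == q) e$b[r] else if (e$b[r] == q) e$a[r] else next
    if (!nb %in% names(ann) || nb %in% exclude) next
    for (f in ann[[nb]])
      s[as.character(f)] <- s[as.character(f)] + e$confidence[r]
  }
  s
}

# Loop-and-sort reimplementation of the leave-one-out order accuracies and
# coverage curve (index tie policy only).
oracle_jackknife <- function(net, ann, vocab) {
  proteins <- sort(names(ann))
  Fn <- nrow(vocab)
  acc <- numeric(Fn)
  curve <- numeric(Fn)
  for (p in proteins) {
    s <- oracle_score(p, net, ann, vocab, exclude = p)
    perm <- vocab$type[order(-s, seq_len(Fn))]
    predictable <- any(s > 0)
    hit <- perm %in% ann[[p]] & predictable
    acc <- acc + hit
    for (k in seq_len(Fn))
      curve[k] <- curve[k] + (predictable && all(ann[[p]] %in% perm[1:k]))
  }
  list(order_accuracy = acc / length(proteins),
       coverage_curve = curve / length(proteins))
}

# Random annotated network built from raw base-R draws (not the package
# generator): n proteins, F fluids, random label subsets, random edges.
random_instance <- function(seed, n = 20, n_fluids = 5, edge_prob = 0.25) {
  set.seed(seed)
  vocab <- fluid_vocabulary(seq_len(n_fluids), paste0("F", seq_len(n_fluids)))
  ids <- paste0("P", seq_len(n))
  sets <- lapply(seq_len(n), function(i)
    sort(sample.int(n_fluids, sample.int(n_fluids, 1L))))
  ann <- fluid_annotations(stats::setNames(sets, ids), vocab)
  pair <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pair)) < edge_prob
  net <- if (any(keep)) {
    ppi_network(ids[pair[1L, keep]], ids[pair[2L, keep]],
                stats::runif(sum(keep), 0.05, 1), nodes = ids)
  } else {
    ppi_network(nodes = ids)
  }
  list(network = net, annotations = ann, vocab = vocab)
}
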