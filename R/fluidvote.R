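#' Fit a weighted-vote body-fluid predictor
#'
#' Binds a weighted PPI network to a body-fluid annotation table to form a
#' guilt-by-association predictor: a query protein's likelihood of secretion
#' into each fluid is the confidence-weighted vote of its annotated
#' interaction partners (strictly one hop — no propagation). "Fitting" here
#' is validation plus indexing; the model is non-parametric and the
#' annotated network *is* the model, which is why leave-one-out evaluation
#' ([jackknife_evaluate()]) needs no retraining.
#'
#' @param network a [ppi_network()] (or a path passed through
#'   [read_network()]).
#' @param annotations a [fluid_annotations()] (or a path passed through
#'   [read_annotations()]).
#' @param vocab a [fluid_vocabulary()]; defaults to the vocabulary attached
#'   to `annotations`.
#' @param min_overlap minimum fraction of network proteins that must be
#'   annotated; below it the inputs almost surely use mismatched identifier
#'   schemes and fitting stops with an error. Default 0 (warn only at 0
#'   overlap).
#' @return An object of class `fluidvote`: a list with the validated
#'   `network`, `annotations`, `vocab`, and the sorted id vector `training`
#'   (annotated proteins present in the network, whose votes carry
#'   evidence).
#' @seealso [predict.fluidvote()], [jackknife_evaluate()],
#'   [simulate.fluidvote()]
#' @export
#' @examples
#' ex <- pgrp1_example()
#' fit <- fluidvote(ex$network, ex$annotations)
#' predict(fit, "O75594", top_k = 3)
fluidvote <- function(network, annotations, vocab = NULL, min_overlap = 0) {
  if (is.character(network)) network <- read_network(network)
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations,
                                    vocab = if (is.null(vocab)) body_fluids()
                                            else vocab)
  }
  stopifnot(inherits(network, "ppi_network"),
            inherits(annotations, "fluid_annotations"))
  if (is.null(vocab)) vocab <- attr(annotations, "vocab")
  stopifnot(inherits(vocab, "fluid_vocabulary"))
  bad <- setdiff(unlist(annotations, use.names = FALSE), vocab$type)
  if (length(bad))
    stop("annotation uses fluid number(s) outside the vocabulary: ",
         paste(utils::head(bad, 3L), collapse = ", "))
  training <- sort(intersect(network$nodes, names(annotations)))
  if (length(network$nodes)) {
    frac <- length(training) / length(network$nodes)
    if (frac < min_overlap)
      stop(sprintf(
        "only %.1f%% of network proteins are annotated (threshold %.1f%%); %s",
        100 * frac, 100 * min_overlap,
        "network and annotation identifiers probably do not match"))
    if (length(training) == 0L)
      warning("no network protein is annotated; every query will be unpredictable")
  }
  structure(list(network = network, annotations = annotations, vocab = vocab,
                 training = training),
            class = "fluidvote")
}

#' @export
print.fluidvote <- function(x, ...) {
  cat("Weighted-vote body-fluid predictor\n")
  cat("  Network:     ", length(x$network$nodes), " proteins, ",
      nrow(x$network$edges), " weighted interactions\n", sep = "")
  cat("  Annotations: ", length(x$annotations), " proteins over ",
      nrow(x$vocab), " fluids (", length(x$training),
      " annotated proteins in the network)\n", sep = "")
  invisible(x)
}

#' Summarize a fitted body-fluid predictor
#'
#' @param object a [fluidvote()] fit.
#' @param ... ignored.
#' @return A list of class `summary.fluidvote` with network and annotation
#'   census figures: protein/edge counts, per-fluid annotation counts,
#'   average label count and the corresponding random-guess baseline.
#' @export
summary.fluidvote <- function(object, ...) {
  ann <- object$annotations
  nbar <- average_label_count(ann)
  per_fluid <- vapply(object$vocab$type,
                      function(f) sum(vapply(ann, function(s) f %in% s,
                                             logical(1L))), 1L)
  structure(list(
    n_network = length(object$network$nodes),
    n_edges = nrow(object$network$edges),
    n_annotated = length(ann),
    n_training = length(object$training),
    per_fluid = stats::setNames(per_fluid, object$vocab$name),
    avg_labels = nbar,
    random_baseline = random_baseline(nbar, nrow(object$vocab))
  ), class = "summary.fluidvote")
}

#' @export
print.summary.fluidvote <- function(x, ...) {
  cat("Weighted-vote body-fluid predictor\n")
  cat("  Network: ", x$n_network, " proteins / ", x$n_edges, " edges; ",
      x$n_training, " annotated in-network proteins\n", sep = "")
  cat("  Annotated proteins: ", x$n_annotated,
      sprintf(" (average %.2f fluids each; random-guess baseline %.2f%%)\n",
              x$avg_labels, x$random_baseline), sep = "")
  cat("  Annotations per fluid:\n")
  print(x$per_fluid)
  invisible(x)
}

#' Ranked body-fluid predictions for query proteins
#'
#' Scores each query by the weighted neighbour vote ([score_all()]) and
#' returns the full descending-order fluid ranking per query. Queries
#' without annotated interaction partners carry zero evidence and are
#' returned with `predictable = FALSE` (their ranking is the tie-policy
#' ordering, not a real prediction).
#'
#' @param object a [fluidvote()] fit.
#' @param queries character vector of query ids; defaults to every annotated
#'   protein in the network (self-prediction over the training set).
#' @param tie_policy,seed tie handling, as in [rank_fluids()].
#' @param top_k optional truncation: keep only the first `top_k` orders per
#'   query.
#' @param exclude protein ids whose annotations are withheld from voting.
#' @param ... ignored.
#' @return A data frame of class `fluidvote_predictions` with columns
#'   `query`, `order` (1..F), `fluid`, `name`, `score`, `predictable`, rows
#'   grouped by query in ascending order.
#' @export
predict.fluidvote <- function(object, queries = NULL,
                              tie_policy = c("index", "random"), seed = NULL,
                              top_k = NULL, exclude = NULL, ...) {
  tie_policy <- match.arg(tie_policy)
  if (is.null(queries)) queries <- object$training
  queries <- as.character(queries)
  Fn <- nrow(object$vocab)
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1L || top_k > Fn)
      stop("'top_k' must lie in 1..", Fn)
  }
  S <- score_all(queries, object$network, object$annotations, object$vocab,
                 exclude = exclude)
  if (tie_policy == "random" && !is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(queries), function(i) {
    rp <- rank_fluids(S[i, ], object$vocab, tie_policy = tie_policy)
    keep <- seq_len(if (is.null(top_k)) Fn else top_k)
    data.frame(query = queries[i], order = keep, fluid = rp$order[keep],
               name = object$vocab$name[match(rp$order[keep],
                                              object$vocab$type)],
               score = rp$scores[keep], predictable = rp$predictable,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), order = integer(), fluid = integer(),
               name = character(), score = numeric(),
               predictable = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, vocab = object$vocab,
            class = c("fluidvote_predictions", "data.frame"))
}

#' @export
print.fluidvote_predictions <- function(x, ...) {
  n_q <- length(unique(x$query))
  cat("Ranked fluid predictions for ", n_q, " quer",
      if (n_q == 1L) "y" else "ies", "\n", sep = "")
  if (any(!x$predictable))
    cat("  (", length(unique(x$query[!x$predictable])),
        " unpredictable: no annotated interaction partner)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate benchmarks resembling a fitted predictor's data
#'
#' Parametric-bootstrap-style generator: estimates the fit's empirical
#' label-size distribution, its within/cross-label edge densities and
#' confidence ranges, and draws synthetic annotated networks from
#' [generate_benchmark()] under those estimates. Useful for judging how
#' evaluation metrics behave on data shaped like yours.
#'
#' @param object a [fluidvote()] fit with at least two annotated network
#'   proteins.
#' @param nsim number of benchmarks to generate.
#' @param seed integer seed (each replicate uses `seed + replicate - 1`).
#' @param ... ignored.
#' @return A list of `nsim` benchmarks (each a list with `network`,
#'   `annotations`, `config`).
#' @export
simulate.fluidvote <- function(object, nsim = 1, seed = NULL, ...) {
  ids <- object$training
  n <- length(ids)
  if (n < 2L) stop("need at least 2 annotated network proteins to simulate")
  Fn <- nrow(object$vocab)
  sizes <- tabulate(label_count(object$annotations, ids), nbins = Fn)
  A <- annotation_matrix(object$annotations, ids, object$vocab)
  share <- (A %*% t(A))[upper.tri(diag(n))] > 0
  e <- object$network$edges
  e <- e[e$a %in% ids & e$b %in% ids, , drop = FALSE]
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  M[cbind(e$a, e$b)] <- TRUE
  has_edge <- (M | t(M))[upper.tri(M)]
  p_in <- if (any(share)) mean(has_edge[share]) else 0
  p_out <- if (any(!share)) mean(has_edge[!share]) else 0
  conf <- range(if (nrow(e)) e$confidence else c(0.15, 1))
  cfg <- synthetic_config(
    n_proteins = n, n_fluids = Fn,
    label_count_probs = sizes / sum(sizes),
    p_in = max(p_in, p_out), p_out = min(p_in, p_out),
    conf_in = conf, conf_out = conf,
    vocab = object$vocab)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  lapply(seq_len(nsim), function(r) {
    cfg$seed <- as.integer(seed + r - 1L)
    generate_benchmark(cfg)
  })
}
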