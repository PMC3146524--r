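# Weighted-vote scoring: a query's likelihood score for fluid j is the sum of
# interaction confidences to its annotated neighbours carrying fluid j.
# Equivalently, the score matrix is the (query x protein) confidence matrix
# times the (protein x fluid) indicator matrix.

#' Score one query protein against every fluid
#'
#' For query `q`, the score of fluid `j` is the sum of `w(q, t)` over
#' annotated neighbours `t` of `q` whose fluid set contains `j`, where `w` is
#' the interaction confidence. Unannotated neighbours contribute nothing;
#' a query with no annotated neighbour receives the zero vector and is
#' flagged unpredictable downstream. The weighted vote counts both how many
#' partners occur in a fluid and how confidently they interact.
#'
#' @param q a single protein id (need not be in the network).
#' @param net a [ppi_network()].
#' @param ann a [fluid_annotations()].
#' @param vocab vocabulary (defaults to the one attached to `ann`).
#' @param exclude protein ids whose annotations must not contribute (used by
#'   the leave-one-out evaluation; excluding `q` itself is a no-op because
#'   the network has no self-interactions).
#' @return Named numeric vector of length `F` (names = fluid type numbers),
#'   all entries >= 0.
#' @export
#' @examples
#' ex <- pgrp1_example()
#' s <- score_query("O75594", ex$network, ex$annotations)
#' s[c("6", "7", "11")]  # plasma/serum, saliva, urine
score_query <- function(q, net, ann, vocab = attr(ann, "vocab"),
                        exclude = NULL) {
  stopifnot(length(q) == 1L)
  score_all(q, net, ann, vocab, exclude)[1L, ]
}

#' Score many query proteins at once
#'
#' Matrix form of [score_query()]: the sparse query-by-protein confidence
#' matrix multiplied by the protein-by-fluid indicator matrix, accumulated
#' in a fixed (sorted) order for reproducibility.
#'
#' @param queries character vector of distinct query protein ids.
#' @inheritParams score_query
#' @return Numeric matrix, one row per query (rownames = queries, colnames =
#'   fluid type numbers), all entries >= 0.
#' @export
score_all <- function(queries, net, ann, vocab = attr(ann, "vocab"),
                      exclude = NULL) {
  stopifnot(inherits(net, "ppi_network"), inherits(ann, "fluid_annotations"))
  queries <- as.character(queries)
  if (anyDuplicated(queries))
    stop("duplicate query id: ", queries[duplicated(queries)][1L])
  Fn <- nrow(vocab)
  S <- matrix(0, nrow = length(queries), ncol = Fn,
              dimnames = list(queries, vocab$type))
  if (length(queries) == 0L || nrow(net$edges) == 0L) return(S)

  inc <- incidence_table(net)
  inc <- inc[inc$protein %in% queries &
             inc$neighbour %in% names(ann) &
             !(inc$neighbour %in% exclude), , drop = FALSE]
  if (nrow(inc) == 0L) return(S)
  # expand each (query, neighbour, w) into one row per fluid of the neighbour
  reps <- lengths(ann[inc$neighbour])
  i <- rep.int(match(inc$protein, queries), reps)
  j <- match(unlist(ann[inc$neighbour], use.names = FALSE), vocab$type)
  x <- rep.int(inc$confidence, reps)
  acc <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(length(queries), Fn))
  S[] <- as.matrix(acc)
  S
}

#' Most likely fluid for a score vector
#'
#' The fluid attaining the maximum score; among tied maxima the lowest fluid
#' type number wins under the default deterministic policy. An all-zero
#' vector has no evidence and returns `NA` with attribute
#' `predictable = FALSE` rather than an arbitrary fluid.
#'
#' @param scores numeric score vector of length `F`.
#' @param vocab a [fluid_vocabulary()] with `F` rows.
#' @return A fluid type number, or `NA_integer_` (attribute `predictable`)
#'   when all scores are zero.
#' @export
top_fluid <- function(scores, vocab = body_fluids()) {
  rp <- rank_fluids(scores, vocab)
  if (!rp$predictable)
    return(structure(NA_integer_, predictable = FALSE))
  rp$order[1L]
}

#' Rank all fluids for a score vector
#'
#' Arranges the fluids in descending score order, producing the full ranked
#' prediction: the fluid in position `j` is the `j`-th order predicted body
#' fluid. Exact ties are broken by ascending fluid type number
#' (`tie_policy = "index"`, the reproducible default) or by a seeded random
#' shuffle (`tie_policy = "random"`).
#'
#' @param scores numeric score vector of length `F`, entries >= 0.
#' @param vocab a [fluid_vocabulary()].
#' @param tie_policy `"index"` or `"random"`.
#' @param seed optional integer seed for the random tie policy.
#' @return A list of class `ranked_fluids`: `order` (permutation of the
#'   fluid type numbers), `scores` (non-increasing), `predictable` (`TRUE`
#'   if any score is positive).
#' @export
rank_fluids <- function(scores, vocab = body_fluids(),
                        tie_policy = c("index", "random"), seed = NULL) {
  tie_policy <- match.arg(tie_policy)
  Fn <- nrow(vocab)
  scores <- as.numeric(scores)
  if (length(scores) != Fn)
    stop("score vector length ", length(scores), " != vocabulary size ", Fn)
  if (anyNA(scores) || any(scores < 0))
    stop("scores must be non-negative and non-missing")
  tiebreak <- if (tie_policy == "index") {
    seq_len(Fn)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample.int(Fn)
  }
  perm <- order(-scores, tiebreak)
  structure(list(order = vocab$type[perm],
                 scores = scores[perm],
                 predictable = any(scores > 0)),
            class = "ranked_fluids")
}

#' @export
print.ranked_fluids <- function(x, ...) {
  cat("Ranked fluids", if (!x$predictable) " (unpredictable: no evidence)",
      ":\n", sep = "")
  print(data.frame(order = seq_along(x$order), fluid = x$order,
                   score = x$scores), row.names = FALSE)
  invisible(x)
}

#' Count annotated neighbours overlapping a fluid set
#'
#' How many annotated interaction partners of `q` are themselves secreted
#' into at least one fluid of `fluids`. With an empty fluid set the count is
#' zero.
#'
#' @inheritParams score_query
#' @param fluids vector of fluid type numbers (subset of the vocabulary).
#' @return A non-negative integer.
#' @export
#' @examples
#' ex <- pgrp1_example()
#' count_neighbors_with_any("O75594", ex$network, ex$annotations,
#'                          c(6, 7, 11))  # 20 of the 23 partners
count_neighbors_with_any <- function(q, net, ann, fluids,
                                     vocab = attr(ann, "vocab")) {
  stopifnot(inherits(net, "ppi_network"), inherits(ann, "fluid_annotations"))
  if (length(fluids)) {
    fluids <- match_fluid_tokens(as.character(fluids), vocab)
  } else {
    fluids <- integer()
  }
  nb <- intersect(names(network_neighbors(net, q)), names(ann))
  sum(vapply(ann[nb], function(s) any(s %in% fluids), logical(1L)))
}
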