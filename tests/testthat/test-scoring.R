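test_that("the worked example scores match the brute-force oracle and the
           frozen hand-derived values", {
  ex <- pgrp1_example()
  s <- score_query("O75594", ex$network, ex$annotations)
  oracle <- oracle_score("O75594", ex$network, ex$annotations, ex$vocab)
  expect_equal(s, oracle, tolerance = 1e-12)
  # frozen regression values, re-derived by summing the fixture's
  # confidence column per fluid
  expect_equal(unname(s[c("6", "7", "11", "2")]),
               c(4.282, 2.202, 2.126, 0.532), tolerance = 1e-12)
})

test_that("degenerate queries score sensibly", {
  ex <- pgrp1_example()
  # isolated / unknown protein: zero vector, unpredictable
  s0 <- score_query("NOT_IN_NETWORK", ex$network, ex$annotations)
  expect_equal(unname(s0), rep(0, 11))
  expect_true(is.na(top_fluid(s0, ex$vocab)))
  expect_false(attr(top_fluid(s0, ex$vocab), "predictable"))

  # single neighbour with one fluid: one-term sum
  net <- ppi_network("Q", "T", 0.4)
  ann <- fluid_annotations(list(T = 3), ex$vocab)
  s1 <- score_query("Q", net, ann)
  expect_equal(unname(s1), c(0, 0, 0.4, rep(0, 8)))

  # excluding the query itself is a no-op (no self-interaction)
  expect_equal(score_query("O75594", ex$network, ex$annotations),
               score_query("O75594", ex$network, ex$annotations,
                           exclude = "O75594"))
  # excluding all neighbours zeroes the scores
  expect_equal(unname(score_query("O75594", ex$network, ex$annotations,
                                  exclude = ex$network$nodes)),
               rep(0, 11))
})

test_that("matrix scoring equals brute-force accumulation on random
           instances", {
  sizes <- c(5, 9, 14, 20, 27, 35, 43, 50)
  for (seed in 1:8) {
    inst <- random_instance(seed, n = sizes[seed])
    queries <- names(inst$annotations)
    S <- score_all(queries, inst$network, inst$annotations, inst$vocab)
    for (q in queries) {
      expect_equal(S[q, ],
                   oracle_score(q, inst$network, inst$annotations,
                                inst$vocab),
                   tolerance = 1e-12)
    }
    # row-sum conservation: total score = sum over neighbours of w * m(t)
    for (q in queries) {
      nb <- network_neighbors(inst$network, q)
      expected <- sum(nb * lengths(inst$annotations[names(nb)]))
      expect_equal(sum(S[q, ]), expected, tolerance = 1e-12)
    }
  }
})

test_that("score_all validates queries and handles empty input", {
  ex <- pgrp1_example()
  expect_error(score_all(c("A", "A"), ex$network, ex$annotations),
               "duplicate query")
  S <- score_all(character(), ex$network, ex$annotations)
  expect_equal(dim(S), c(0L, 11L))
})

test_that("permuting fluid labels permutes score entries identically", {
  inst <- random_instance(101, n = 15, n_fluids = 6)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)  # fluid f -> perm[f]
  ann2 <- fluid_annotations(
    lapply(unclass(inst$annotations), function(s) sort(perm[s])),
    inst$vocab)
  for (q in names(inst$annotations)) {
    s1 <- score_query(q, inst$network, inst$annotations, inst$vocab)
    s2 <- score_query(q, inst$network, ann2, inst$vocab)
    expect_equal(unname(s2[perm]), unname(s1), tolerance = 1e-12)
  }
})

test_that("adding a neighbour with fluid j raises only score j", {
  inst <- random_instance(7, n = 10, n_fluids = 4)
  q <- "P1"
  before <- score_query(q, inst$network, inst$annotations, inst$vocab)
  e <- inst$network$edges
  net2 <- ppi_network(c(e$a, q), c(e$b, "NEW"), c(e$confidence, 0.7))
  ann2 <- fluid_annotations(c(unclass(inst$annotations), list(NEW = 2)),
                            inst$vocab)
  after <- score_query(q, net2, ann2, inst$vocab)
  expect_equal(after[["2"]], before[["2"]] + 0.7, tolerance = 1e-12)
  expect_equal(after[-2], before[-2], tolerance = 1e-12)
})

test_that("ranking is a descending permutation with lawful tie handling", {
  v <- body_fluids()
  ex_scores <- score_query("O75594", pgrp1_example()$network,
                           pgrp1_example()$annotations)
  rp <- rank_fluids(ex_scores, v)
  expect_equal(rp$order[1:3], c(6L, 7L, 11L))
  expect_setequal(rp$order, v$type)               # bijection
  expect_true(all(diff(rp$scores) <= 0))          # non-increasing
  # prefix property: first k entries are the k largest scores
  for (k in c(1, 4, 8))
    expect_equal(sum(rp$scores[1:k]),
                 sum(sort(ex_scores, decreasing = TRUE)[1:k]))

  # illustrative ordering: s3 > s6 > s11 > rest
  s <- stats::setNames(rep(0.1, 11), v$type)
  s[c("3", "6", "11")] <- c(0.9, 0.8, 0.7)
  expect_equal(rank_fluids(s, v)$order[1:3], c(3L, 6L, 11L))

  # all-equal scores: index policy yields 1..11, random policy a seeded
  # reproducible permutation
  u <- rep(1, 11)
  expect_equal(rank_fluids(u, v)$order, 1:11)
  expect_equal(top_fluid(u, v), 1L)
  r1 <- rank_fluids(u, v, tie_policy = "random", seed = 99)$order
  r2 <- rank_fluids(u, v, tie_policy = "random", seed = 99)$order
  expect_identical(r1, r2)
  expect_setequal(r1, 1:11)

  expect_equal(top_fluid(c(rep(0, 8), 1, 0, 0), v), 9L)
  expect_error(rank_fluids(rep(0.5, 10), v), "vocabulary size")
  expect_error(rank_fluids(c(rep(0.5, 10), -1), v), "non-negative")
})

test_that("the indicator matrix mirrors the annotation sets", {
  ex <- pgrp1_example()
  A <- annotation_matrix(ex$annotations)
  expect_equal(dim(A), c(24L, 11L))
  expect_equal(unname(rowSums(A)),
               unname(lengths(ex$annotations[rownames(A)])))
  expect_equal(unname(A["O75594", ]),
               as.integer(1:11 %in% c(6, 7, 11)))
  # among the 23 interaction partners, 18 carry plasma/serum
  expect_equal(sum(A[setdiff(rownames(A), "O75594"), "6"]), 18L)
  expect_error(annotation_matrix(ex$annotations, "MISSING"),
               "not annotated")
})

test_that("neighbour overlap counting matches the worked example", {
  ex <- pgrp1_example()
  expect_equal(count_neighbors_with_any("O75594", ex$network,
                                        ex$annotations, c(6, 7, 11)), 20L)
  # the complement: partners disjoint from plasma/serum, saliva, urine
  nb <- names(network_neighbors(ex$network, "O75594"))
  disjoint <- sum(vapply(ex$annotations[nb],
                         function(s) !any(s %in% c(6, 7, 11)), logical(1)))
  expect_equal(disjoint, 3L)
  expect_equal(count_neighbors_with_any("O75594", ex$network,
                                        ex$annotations, integer()), 0L)
})
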