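triangle_fit <- function() {
  vocab <- fluid_vocabulary(1:3, c("A", "B", "C"))
  net <- ppi_network(c("P1", "P1", "P2"), c("P2", "P3", "P3"),
                     rep(0.5, 3))
  ann <- fluid_annotations(list(P1 = 2, P2 = 2, P3 = 2), vocab)
  fluidvote(net, ann, vocab)
}

test_that("unanimous neighbours give perfect first-order accuracy", {
  ev <- jackknife_evaluate(triangle_fit())
  expect_equal(unname(ev$order_accuracy), c(1, 0, 0))
  expect_equal(ev$coverage_curve[["L1"]], 1)
  expect_equal(ev$avg_labels, 1)
  expect_equal(ev$k, 2L)
})

test_that("anti-homophilic pair fails the first order entirely", {
  vocab <- fluid_vocabulary(1:3, c("A", "B", "C"))
  net <- ppi_network("P1", "P2", 0.8)
  ann <- fluid_annotations(list(P1 = 1, P2 = 2), vocab)
  ev <- jackknife_evaluate(fluidvote(net, ann, vocab))
  expect_equal(ev$order_accuracy[["ACC1"]], 0)  # each predicts the other's fluid
  expect_equal(ev$order_accuracy[["ACC2"]], 1)
})

test_that("jackknife metrics equal the loop-and-sort oracle on random
           instances", {
  for (seed in c(3, 17, 29)) {
    inst <- random_instance(seed, n = 20)
    fit <- fluidvote(inst$network, inst$annotations, inst$vocab)
    ev <- jackknife_evaluate(fit)
    oracle <- oracle_jackknife(inst$network, inst$annotations, inst$vocab)
    expect_equal(unname(ev$order_accuracy), oracle$order_accuracy,
                 tolerance = 1e-12)
    expect_equal(unname(ev$coverage_curve), oracle$coverage_curve,
                 tolerance = 1e-12)
  }
})

test_that("average label count follows its definition and the census", {
  expect_equal(round(average_label_count(body_fluid_census()), 2), 3.23)
  v <- fluid_vocabulary(1:3, c("A", "B", "C"))
  expect_equal(average_label_count(
    fluid_annotations(list(X = 1, Y = 2), v)), 1)
  expect_equal(average_label_count(
    fluid_annotations(list(X = c(1, 2), Y = 3), v)), 1.5)
  expect_error(average_label_count(fluid_annotations(list(X = 1), v),
                                   proteins = character()), "empty")
})

test_that("the random-guess baseline is avg labels over fluid count", {
  expect_equal(round(random_baseline(3.23, 11), 2), 29.36)
  expect_equal(random_baseline(11, 11), 100)
  expect_equal(random_baseline(1, 4), 25)
  expect_error(random_baseline(3, 0), "positive")
  expect_error(random_baseline(5, 4), "lie in")
})

test_that("the coverage window k is floor(avg) + 1", {
  expect_equal(choose_k(3.23), 4L)
  expect_equal(choose_k(1.0), 2L)
  expect_equal(choose_k(0.5), 1L)
  expect_error(choose_k(-1), "non-negative")
})

test_that("coverage likelihood checks full containment in the top k", {
  ex <- pgrp1_example()
  fit <- fluidvote(ex$network, ex$annotations)
  preds <- predict(fit)
  Fn <- 11L
  expect_equal(coverage_likelihood(preds, ex$annotations, Fn), 1)
  # independent subset check at k = 4
  k <- 4L
  manual <- mean(vapply(unique(preds$query), function(q) {
    top <- preds$fluid[preds$query == q & preds$order <= k]
    all(ex$annotations[[q]] %in% top)
  }, logical(1)))
  expect_equal(coverage_likelihood(preds, ex$annotations, k), manual)
  expect_error(coverage_likelihood(preds, ex$annotations, 0), "1..11")
  expect_error(coverage_likelihood(preds, ex$annotations, 12), "1..11")
})

test_that("an isolated annotated protein is unpredictable and fails
           everywhere", {
  vocab <- fluid_vocabulary(1:3, c("A", "B", "C"))
  net <- ppi_network(nodes = "P1")
  ann <- fluid_annotations(list(P1 = 2), vocab)
  ev <- jackknife_evaluate(fluidvote(net, ann, vocab))
  expect_equal(ev$n_unpredictable, 1L)
  expect_equal(unname(ev$order_accuracy), c(0, 0, 0))
  expect_equal(unname(ev$coverage_curve), c(0, 0, 0))
})

test_that("dropping unpredictable proteins changes the denominator", {
  vocab <- fluid_vocabulary(1:2, c("A", "B"))
  net <- ppi_network("P1", "P2", 0.9, nodes = "P3")
  ann <- fluid_annotations(list(P1 = 1, P2 = 1, P3 = 2), vocab)
  fit <- fluidvote(net, ann, vocab)
  kept <- jackknife_evaluate(fit)
  expect_equal(kept$n_evaluated, 3L)
  expect_equal(kept$order_accuracy[["ACC1"]], 2 / 3)
  dropped <- jackknife_evaluate(fit, drop_unpredictable = TRUE)
  expect_equal(dropped$n_evaluated, 2L)
  expect_equal(dropped$order_accuracy[["ACC1"]], 1)
  expect_equal(sum(dropped$order_accuracy), dropped$avg_labels)
})

test_that("evaluation demands a fully annotated network", {
  vocab <- fluid_vocabulary(1:2, c("A", "B"))
  net <- ppi_network("P1", "P2", 0.5)
  ann <- fluid_annotations(list(P1 = 1), vocab)
  expect_error(jackknife_evaluate(fluidvote(net, ann, vocab)),
               "without annotation")
})

test_that("conservation, ranges and coverage monotonicity hold across a
           property sweep", {
  for (seed in 1:25) {
    bench <- generate_benchmark(
      synthetic_config(n_proteins = 10 + (seed %% 4) * 10,
                       n_fluids = c(3, 5, 11)[1 + seed %% 3],
                       p_in = 0.4, p_out = 0.1, seed = seed))
    ev <- jackknife_evaluate(fluidvote(bench$network, bench$annotations,
                                       bench$config$vocab))
    expect_true(all(ev$order_accuracy >= 0 & ev$order_accuracy <= 1))
    expect_true(ev$avg_labels >= 1)
    expect_true(ev$random_baseline > 0 && ev$random_baseline <= 100)
    expect_true(ev$k >= 1)
    expect_true(all(diff(ev$coverage_curve) >= -1e-12))  # monotone L_k
    if (ev$n_unpredictable == 0L) {
      expect_equal(sum(ev$order_accuracy), ev$avg_labels,
                   tolerance = 1e-12)
      expect_equal(ev$coverage_curve[[length(ev$coverage_curve)]], 1)
    }
  }
})

test_that("identical inputs and tie seed reproduce the report exactly", {
  bench <- generate_benchmark(synthetic_config(n_proteins = 30, seed = 5))
  fit <- fluidvote(bench$network, bench$annotations)
  e1 <- jackknife_evaluate(fit, tie_policy = "random", seed = 123)
  e2 <- jackknife_evaluate(fit, tie_policy = "random", seed = 123)
  expect_identical(e1, e2)
})
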