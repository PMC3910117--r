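# Small helper: build a dataset of noisy copies of two distinct curves.
two_cluster_toy <- function(n_per = 12, sd = 0.05, seed = 17) {
  set.seed(seed)
  p1 <- model_params(-0.02, 0.5, 2, 0.5, 0, 0)
  p2 <- model_params(-0.02, 1.3, -1.5, 1, 0.05, 0.5)
  mat <- rbind(
    t(replicate(n_per, evaluate_model(p1, 18) + rnorm(18, sd = sd))),
    t(replicate(n_per, evaluate_model(p2, 18) + rnorm(18, sd = sd))))
  list(mat = mat, params = list(p1, p2), truth = rep(1:2, each = n_per))
}

test_that("cluster cost is zero on exact curves and additive otherwise", {
  p1 <- model_params(0, 1, 1, 0, 0, 0)
  p2 <- model_params(0, 1, 0, 1, 0, 2)
  exact <- rbind(evaluate_model(p1, 10), evaluate_model(p2, 10))
  expect_equal(cluster_cost(exact, c(1, 2), list(p1, p2)), 0)

  # hand computation on a 2-profile, m = 3 toy
  off <- exact[, 1:3] + matrix(c(0.1, -0.2, 0.3, 0.4, -0.5, 0.6), 2, 3)
  p1_3 <- direct_curve(0, 1, 1, 0, 0, 0, 3)
  p2_3 <- direct_curve(0, 1, 0, 1, 0, 2, 3)
  hand <- sum((off[1, ] - p1_3)^2) + sum((off[2, ] - p2_3)^2)
  expect_equal(cluster_cost(off, c(1, 2), list(p1, p2)), hand)

  expect_error(cluster_cost(exact, c(1, 3), list(p1, p2)), "unknown")
})

test_that("K = 1 cost equals the pooled single-model residual", {
  toy <- two_cluster_toy()
  est <- estimate_cluster_params(toy$mat)
  expect_false(est$degenerate)
  curve <- evaluate_model(est$params, ncol(toy$mat))
  expect_equal(cluster_cost(toy$mat, rep(1, nrow(toy$mat)), list(est$params)),
               sum(sweep(toy$mat, 2, curve)^2))
})

test_that("pooled estimation reduces to the single-profile fit", {
  set.seed(23)
  x <- evaluate_model(model_params(-0.05, 0.9, 1, -0.5, 0.02, 0.3), 18) +
    rnorm(18, sd = 0.2)
  single <- fit_profile(x)
  pooled <- estimate_cluster_params(matrix(x, nrow = 1))
  expect_equal(unlist(pooled$params), unlist(single$params))
  # identical copies change nothing: the normal equations just scale
  copies <- matrix(x, nrow = 7, ncol = 18, byrow = TRUE)
  expect_equal(unlist(estimate_cluster_params(copies)$params),
               unlist(single$params), tolerance = 1e-9)
})

test_that("pooled estimates tighten as the cluster grows", {
  # pooling averages the noise out of the normal equations: the sampling
  # spread of the estimate shrinks with cluster size (the small
  # finite-difference bias common to all members does not, so spread --
  # not error to truth -- is the scaling property to check)
  truth <- model_params(-0.05, 0.8, 1.5, -0.8, 0.05, 0.4)
  gen <- function(n, sd, seed) {
    set.seed(seed)
    t(replicate(n, evaluate_model(truth, 60, 0.3) + rnorm(60, sd = sd)))
  }
  spread <- function(n) {
    ests <- t(sapply(1:8, function(s) {
      unlist(estimate_cluster_params(gen(n, 0.2, 100 + s), 0.3)$params)
    }))
    sqrt(sum(apply(ests, 2, var)))
  }
  expect_lt(spread(60), spread(3) / 2)
  # and at low noise the pooled estimate sits close to the generator
  est <- estimate_cluster_params(gen(20, 0.01, 1), 0.3)
  expect_lt(sqrt(sum((unlist(est$params) - unlist(truth))^2)), 0.1)
})

test_that("assignment picks the nearest curve with lowest-index ties", {
  p1 <- model_params(0, 1, 1, 0, 0, 0)
  p2 <- model_params(0, 1, 0, 1, 0, 2)
  x2 <- evaluate_model(p2, 12)
  expect_equal(assign_profiles(rbind(x2), list(p1, p2)), 2L)
  # exact tie between identical models 1 and 3 breaks to 1
  expect_equal(assign_profiles(rbind(x2), list(p2, p1, p2)), 1L)
  # degenerate clusters are skipped
  expect_equal(assign_profiles(rbind(x2), list(NULL, p1, p2)), 3L)
  expect_error(assign_profiles(rbind(x2), list(NULL, NULL)), "degenerate")
})

test_that("assignment under the true models recovers the generating labels", {
  toy <- two_cluster_toy()
  labels <- assign_profiles(toy$mat, toy$params)
  expect_equal(adjusted_rand_index(labels, toy$truth), 1)
})

test_that("a converged partition is a fixed point of the iteration", {
  toy <- two_cluster_toy()
  run1 <- relocate_iterate(toy$mat, K = 2, init = toy$truth)
  expect_true(run1$converged)
  run2 <- relocate_iterate(toy$mat, K = 2, init = run1$labels)
  expect_equal(run2$n_iter, 1L)
  expect_equal(run2$labels, run1$labels)
  expect_equal(run2$cost, run1$cost)
})

test_that("the recorded cost trace never increases", {
  toy <- two_cluster_toy(n_per = 20, sd = 0.4)
  set.seed(29)
  for (r in 1:8) {
    init <- sample.int(3, nrow(toy$mat), replace = TRUE)
    run <- suppressWarnings(relocate_iterate(toy$mat, K = 3, init = init))
    expect_true(all(diff(run$cost_trace) <= 1e-10))
    expect_equal(sum(run$sizes), nrow(toy$mat))
  }
})

test_that("relabelling the initial partition permutes the output labels", {
  toy <- two_cluster_toy(n_per = 10, sd = 0.2, seed = 37)
  init <- rep(c(1L, 2L, 3L), length.out = nrow(toy$mat))
  perm <- c(3L, 1L, 2L)
  run_a <- suppressWarnings(relocate_iterate(toy$mat, 3, init))
  run_b <- suppressWarnings(relocate_iterate(toy$mat, 3, perm[init]))
  expect_equal(perm[run_a$labels], run_b$labels)
  expect_equal(run_a$cost, run_b$cost)
})

test_that("well-separated clusters are recovered from random restarts", {
  toy <- two_cluster_toy()
  cl <- cluster_with_restarts(toy$mat, K = 2, n_restarts = 10, seed = 5)
  expect_equal(adjusted_rand_index(cl$labels, toy$truth), 1)
  expect_length(cl$restart_labels, 10)
  expect_equal(cl$cost, min(cl$restart_costs))
})

test_that("restart runs are reproducible under a fixed seed", {
  toy <- two_cluster_toy()
  a <- cluster_with_restarts(toy$mat, 2, n_restarts = 3, seed = 99)
  b <- cluster_with_restarts(toy$mat, 2, n_restarts = 3, seed = 99)
  expect_identical(a$labels, b$labels)
  expect_identical(a$restart_costs, b$restart_costs)
  expect_identical(a$restart_labels, b$restart_labels)
})

test_that("k-means initialisation is supported and labelled tables emerge", {
  toy <- two_cluster_toy()
  cl <- cluster_with_restarts(toy$mat, 2, n_restarts = 3,
                              init_mode = "kmeans", seed = 12)
  expect_equal(adjusted_rand_index(cl$labels, toy$truth), 1)
  tab <- cluster_param_table(cl)
  expect_equal(names(tab),
               c("cluster", "size", "alpha", "omega", "a", "b", "c", "d"))
  expect_equal(sum(tab$size), nrow(toy$mat))
})
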