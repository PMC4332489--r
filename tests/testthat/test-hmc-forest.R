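random_instance <- function(n, p, L, seed) {
  set.seed(seed)
  list(X = matrix(rbinom(n * p, 1, 0.5), n, p),
       V = matrix(rbinom(n * L, 1, 0.5), n, L),
       w = runif(L, 0.2, 1))
}

test_that("weighted variance matches Bernoulli arithmetic and a brute-force oracle", {
  V <- matrix(c(1, 1, 1), ncol = 1)
  expect_equal(hmc_weighted_variance(V, 1), 0)
  expect_equal(hmc_weighted_variance(matrix(c(0, 1), ncol = 1), 1), 0.25)

  V4 <- matrix(c(1, 0, 1, 0,
                 1, 1, 0, 0,
                 0, 0, 1, 1), nrow = 4)
  w <- c(1, 0.75, 0.5)
  expect_equal(hmc_weighted_variance(V4, w), oracle_weighted_variance(V4, w))

  for (s in 1:10) {
    inst <- random_instance(8, 3, 4, s)
    expect_equal(hmc_weighted_variance(inst$V, inst$w),
                 oracle_weighted_variance(inst$V, inst$w), tolerance = 1e-12)
  }
  expect_error(hmc_weighted_variance(matrix(0, 0, 1), 1), "class vector")
})

test_that("best_split maximizes variance reduction and handles degenerate features", {
  # a perfectly separating feature drives both children pure: gain = Var(V)
  X <- matrix(c(0, 0, 1, 1), ncol = 1)
  V <- matrix(c(0, 0, 1, 1), ncol = 1)
  sp <- hmc_best_split(X, V, 1)
  expect_equal(sp$feature, 1L)
  expect_equal(sp$gain, hmc_weighted_variance(V, 1))

  # constant features admit no split
  expect_null(hmc_best_split(matrix(1, 4, 2), V, 1))

  # exhaustive-search equivalence on random small instances
  for (s in 1:40) {
    inst <- random_instance(sample(3:6, 1), sample(2:4, 1), sample(1:3, 1), s)
    got <- hmc_best_split(inst$X, inst$V, inst$w)
    want <- oracle_best_split(inst$X, inst$V, inst$w)
    if (is.null(want)) {
      expect_true(is.null(got) || got$gain <= 1e-12)
    } else {
      expect_equal(got$gain, want$gain, tolerance = 1e-9)
    }
  }

  # min_leaf vetoes splits that would leave a child too small
  X6 <- matrix(c(1, 0, 0, 0, 0, 0), ncol = 1)
  V6 <- matrix(c(1, 0, 0, 0, 0, 0), ncol = 1)
  expect_null(hmc_best_split(X6, V6, 1, min_leaf = 2))
})

test_that("grow_tree stops on pure nodes, replays labels, and is deterministic", {
  inst <- random_instance(20, 5, 2, 99)

  pure <- hmc_grow_tree(inst$X, matrix(1, 20, 2), c(1, 1), seed = 1)
  expect_equal(length(pure$feature), 1L)
  expect_equal(pure$feature, -1L)

  # separable data with all features available reproduces training labels
  set.seed(2)
  X <- matrix(rbinom(60, 1, 0.5), 12, 5)
  X <- X[!duplicated(X), , drop = FALSE]
  V <- cbind(X[, 1] | X[, 3], X[, 2]) * 1
  tree <- hmc_grow_tree(X, V, c(1, 1), mtry = ncol(X), min_leaf = 1, seed = 5)
  pred <- t(apply(X, 1, function(x) r_traverse_leaf(tree, x)))
  expect_equal(unname(pred), unname(V))

  t1 <- hmc_grow_tree(inst$X, inst$V, inst$w, mtry = 2, min_leaf = 2, seed = 42)
  t2 <- hmc_grow_tree(inst$X, inst$V, inst$w, mtry = 2, min_leaf = 2, seed = 42)
  expect_identical(t1$feature, t2$feature)
  expect_identical(t1$leaves, t2$leaves)
})

test_that("forest bagging, OOB assembly and serialization are consistent", {
  inst <- random_instance(40, 6, 3, 7)
  colnames(inst$V) <- paste0("T", 1:3)
  forest <- fit_hmc_forest(inst$X, inst$V, inst$w, n_trees = 25, min_leaf = 2,
                           seed = 3)
  expect_equal(colSums(forest$inbag), rep(40, 25))  # bags have size n

  # T = 1: forest prediction equals the single tree's prediction
  f1 <- fit_hmc_forest(inst$X, inst$V, inst$w, n_trees = 1, min_leaf = 2,
                       seed = 5)
  single <- t(apply(inst$X, 1, function(x) r_traverse_leaf(f1$trees[[1]], x)))
  expect_equal(unname(predict(f1, inst$X)), unname(single))

  # OOB probabilities: replayed in R, averaged over exactly the OOB trees
  oob <- oob_predict(forest, inst$X)
  expect_true(all(oob$prob[oob$coverage > 0, ] >= 0 &
                  oob$prob[oob$coverage > 0, ] <= 1))
  replay <- r_forest_predict(forest, inst$X, oob = TRUE)
  expect_equal(unname(oob$prob), unname(replay), tolerance = 1e-12)
  # an example OOB in exactly one tree inherits that leaf vector verbatim
  once <- which(oob$coverage == 1L)
  for (i in once) {
    t <- which(forest$inbag[i, ] == 0L)
    expect_equal(unname(oob$prob[i, ]),
                 unname(r_traverse_leaf(forest$trees[[t]], inst$X[i, ])))
  }
  expect_error(oob_predict(forest, inst$X[1:10, ]), "rows")

  tf <- withr::local_tempfile(fileext = ".json")
  write_hmc_forest(forest, tf)
  back <- read_hmc_forest(tf)
  expect_equal(unname(oob_predict(back, inst$X)$prob), unname(oob$prob))
})

test_that("bootstrap bags keep ~63% unique and leave ~37% out", {
  fr <- bootstrap_bag_fractions(1000, draws = 500, seed = 1)
  expect_gt(fr$inbag_unique, 0.62)
  expect_lt(fr$inbag_unique, 0.65)
  expect_equal(fr$inbag_unique + fr$oob, 1)
})

test_that("duplicated feature columns do not change predictions when never drawn", {
  inst <- random_instance(30, 4, 2, 13)
  tree_a <- hmc_grow_tree(inst$X, inst$V, inst$w, mtry = 4, min_leaf = 2,
                          seed = 8)
  # duplicate of column 4 appended; with mtry = all, ties break to the
  # lower index so the duplicate never wins a split
  Xdup <- cbind(inst$X, inst$X[, 4])
  tree_b <- hmc_grow_tree(Xdup, inst$V, inst$w, mtry = 5, min_leaf = 2,
                          seed = 8)
  pa <- t(apply(inst$X, 1, function(x) r_traverse_leaf(tree_a, x)))
  pb <- t(apply(Xdup, 1, function(x) r_traverse_leaf(tree_b, x)))
  expect_equal(pa, pb)
})

test_that("stronger family flip noise degrades mean OOB AUPRC monotonically", {
  eps_grid <- c(0, 0.1, 0.25, 0.4)
  means <- vapply(eps_grid, function(eps) {
    w <- simulate_world(G = 25, M = 4, F_per_module = 10, flip_noise = eps,
                        rho = 1, D = 2, B = 2, seed = 31)
    cfg <- experiment_config(n_trees = 60, min_leaf = 1,
                             support_fraction = 0.05, seed = 5)
    prep <- prepare_experiment(w, cfg)
    run_condition(prep, w$genome_ids, forest_seed = 17)$mean
  }, numeric(1))
  expect_lt(cor(eps_grid, means, method = "spearman"), 0)
  expect_gt(means[1], means[length(means)])
})
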