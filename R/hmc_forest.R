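# Hierarchical multi-label random forest over binary profile features.
#
# Class vectors are binary indicators over an ordered term list; because
# annotations are propagated upstream, setting a term implies setting all
# of its ancestors. Trees minimize the hierarchy-weighted class-vector
# variance, so mislabeling a deep (specific) term costs less than
# mislabeling a shallow (general) one.

#' Build binary class vectors from group annotations
#'
#' @param ga A `group_annotations` object.
#' @param group_ids Ordered example (group) ids — typically
#'   `rownames(profiles)`.
#' @param term_order Ordered character vector of terms forming the class
#'   vector; roots should already be excluded by the caller (after
#'   propagation they are 1 for every annotated example and carry no
#'   signal).
#' @return Numeric 0/1 matrix `length(group_ids)` x `length(term_order)`
#'   with dimnames.
#' @export
build_class_vectors <- function(ga, group_ids, term_order) {
  stopifnot(inherits(ga, "group_annotations"))
  V <- matrix(0, nrow = length(group_ids), ncol = length(term_order),
              dimnames = list(group_ids, term_order))
  for (i in seq_along(group_ids)) {
    ts <- intersect(ga$terms[[group_ids[i]]], term_order)
    if (length(ts)) V[i, ts] <- 1
  }
  V
}

#' Hierarchy-weighted variance of a set of class vectors
#'
#' Computes `(1/n) * sum_i sum_c w_c (v_ic - vbar_c)^2` where `vbar` is the
#' component-wise mean — the impurity minimized by the tree split criterion.
#'
#' @param V Numeric matrix, examples x terms.
#' @param w Numeric weight vector, one entry per term column.
#' @return Non-negative scalar.
#' @export
hmc_weighted_variance <- function(V, w) {
  V <- as.matrix(V)
  .cpp_weighted_variance(V, as.numeric(w))
}

#' Best single-feature split by weighted-variance reduction
#'
#' Evaluates each candidate feature and returns the one maximizing
#' `Var(V) - (n0/n) Var(V0) - (n1/n) Var(V1)`. Splits leaving either child
#' with fewer than `min_leaf` examples are not considered; ties are broken
#' toward the lowest feature index. Returns `NULL` when no candidate
#' achieves a positive gain.
#'
#' @param X Binary integer feature matrix (examples x features).
#' @param V Class-vector matrix.
#' @param w Term weights.
#' @param candidate_features Integer vector of 1-based column indices of `X`.
#' @param min_leaf Minimum child size; default 1.
#' @return `list(feature =, gain =)` with a 1-based feature index, or `NULL`.
#' @export
hmc_best_split <- function(X, V, w, candidate_features = seq_len(ncol(X)),
                           min_leaf = 1) {
  res <- .cpp_best_split(binarize(X), as.matrix(V), as.numeric(w),
                         as.integer(candidate_features) - 1L,
                         as.integer(min_leaf))
  if (res$feature < 0) return(NULL)
  list(feature = res$feature + 1L, gain = res$gain)
}

#' Grow a single HMC decision tree
#'
#' Recursive variance-reduction splitting: at each node `mtry` features are
#' drawn without replacement, the best positive-gain split respecting
#' `min_leaf` is taken, and growth stops when no such split exists or the
#' node has fewer than `2 * min_leaf` examples. Leaves store the mean class
#' vector of their training examples. Fully deterministic given `seed`.
#'
#' @inheritParams hmc_best_split
#' @param mtry Features drawn per node.
#' @param seed Integer seed for the tree's private RNG stream.
#' @return A `hmc_tree` list: `feature` (0-based split feature per node, -1
#'   for leaves), `left`/`right` (0-based child node ids; right = feature
#'   value 1), `leaf_of` (row of `leaves` per leaf node) and `leaves`
#'   (leaf x term probability matrix).
#' @export
hmc_grow_tree <- function(X, V, w, mtry = ncol(X), min_leaf = 1, seed = 1) {
  stopifnot(nrow(X) == nrow(V))
  tree <- .cpp_grow_tree(binarize(X), as.matrix(V), as.numeric(w),
                         as.integer(mtry), as.integer(min_leaf),
                         as.numeric(seed))
  structure(tree, class = "hmc_tree")
}

#' Fit a bagged ensemble of HMC trees
#'
#' For each of the `n_trees` trees, `n` example indices are drawn with
#' replacement (bootstrap bagging — on average ~63% of distinct examples
#' land in a bag, leaving ~37% out-of-bag) and a tree is grown on the bagged
#' multiset. Per-tree in-bag counts are recorded so out-of-bag predictions
#' can be assembled later.
#'
#' @inheritParams hmc_grow_tree
#' @param n_trees Ensemble size; default 500.
#' @param mtry Features per split; default `ceiling(sqrt(ncol(X)))`.
#' @param min_leaf Minimum leaf size; default 5.
#' @param seed Master seed; per-tree streams are derived by fixed spawning.
#' @return An `hmc_forest` list: `trees`, `inbag` (n x n_trees bootstrap
#'   count matrix), and `params`.
#' @export
fit_hmc_forest <- function(X, V, w, n_trees = 500,
                           mtry = ceiling(sqrt(ncol(X))), min_leaf = 5,
                           seed = 1) {
  stopifnot(nrow(X) == nrow(V), n_trees >= 1)
  Xb <- binarize(X)
  fit <- .cpp_fit_forest(Xb, as.matrix(V), as.numeric(w),
                         as.integer(n_trees), as.integer(mtry),
                         as.integer(min_leaf), as.numeric(seed))
  structure(
    list(trees = fit$trees, inbag = fit$inbag,
         term_order = colnames(V), n = nrow(X),
         params = list(n_trees = n_trees, mtry = mtry, min_leaf = min_leaf,
                       seed = seed)),
    class = "hmc_forest"
  )
}

#' Predict per-term probabilities with a fitted forest
#'
#' Averages leaf class vectors over all trees.
#'
#' @param object An `hmc_forest`.
#' @param X Binary feature matrix with the same columns the forest was
#'   trained on.
#' @param ... Unused.
#' @return Numeric matrix, examples x terms.
#' @export
predict.hmc_forest <- function(object, X, ...) {
  Xb <- binarize(X)
  coverage <- integer(nrow(Xb))
  pred <- .cpp_predict(object$trees, Xb,
                       matrix(0L, nrow(Xb), length(object$trees)),
                       FALSE, coverage)
  dimnames(pred) <- list(rownames(X), object$term_order)
  pred
}

#' Out-of-bag probability predictions
#'
#' For each training example, averages the leaf vectors of exactly those
#' trees whose bootstrap bag did not contain it — an unbiased estimate of
#' generalization used for all AUPRC scoring. Examples covered by no tree
#' (probability ~ (1-e^-1)^n_trees, negligible for realistic ensembles)
#' get `NA` probabilities and coverage 0; downstream evaluation drops them.
#'
#' @param forest An `hmc_forest`.
#' @param X The training feature matrix the forest was fit on (same row
#'   count).
#' @return List of class `oob_predictions`: `prob` (examples x terms) and
#'   `coverage` (integer vector, trees per example).
#' @export
oob_predict <- function(forest, X) {
  stopifnot(inherits(forest, "hmc_forest"))
  if (nrow(X) != forest$n)
    stop("X has ", nrow(X), " rows but the forest was fit on ", forest$n)
  Xb <- binarize(X)
  coverage <- integer(nrow(Xb))
  prob <- .cpp_predict(forest$trees, Xb, forest$inbag, TRUE, coverage)
  dimnames(prob) <- list(rownames(X), forest$term_order)
  structure(list(prob = prob, coverage = coverage), class = "oob_predictions")
}

#' Bootstrap in-bag / out-of-bag fractions
#'
#' Simulates the bagging step alone: `draws` bootstrap samples of size `n`
#' drawn with replacement from `n` items, reporting the mean fraction of
#' distinct items in the bag and the mean fraction left out-of-bag. For
#' large `n` these approach `1 - 1/e` (63.2%) and `1/e` (36.8%).
#'
#' @param n Number of items (training examples).
#' @param draws Number of bootstrap replicates; default 500.
#' @param seed Integer seed.
#' @return `list(inbag_unique =, oob =)`, both fractions in \[0, 1\].
#' @export
bootstrap_bag_fractions <- function(n, draws = 500, seed = 1) {
  stopifnot(n >= 1, draws >= 1)
  fracs <- with_seed(seed, vapply(seq_len(draws), function(i) {
    length(unique(sample.int(n, n, replace = TRUE))) / n
  }, numeric(1)))
  list(inbag_unique = mean(fracs), oob = 1 - mean(fracs))
}

#' Serialize a fitted forest to JSON
#'
#' Writes `params`, `term_order` and the flat per-tree node arrays
#' (`feature`, `left`, `right`, `leaf_of`, `leaves`) so a forest can be
#' stored and reloaded without refitting. [read_hmc_forest()] inverts it.
#'
#' @param forest An `hmc_forest`.
#' @param path Output JSON path.
#' @export
write_hmc_forest <- function(forest, path) {
  stopifnot(inherits(forest, "hmc_forest"))
  obj <- list(
    params = forest$params,
    term_order = forest$term_order,
    n = forest$n,
    inbag = forest$inbag,
    trees = lapply(forest$trees, function(tr) {
      list(feature = tr$feature, left = tr$left, right = tr$right,
           leaf_of = tr$leaf_of, leaves = tr$leaves)
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a forest serialized by [write_hmc_forest()]
#' @param path JSON path.
#' @return An `hmc_forest`.
#' @export
read_hmc_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- lapply(seq_len(nrow_safe(obj$trees)), function(i) {
    tr <- if (is.data.frame(obj$trees)) lapply(obj$trees, `[[`, i) else obj$trees[[i]]
    list(feature = as.integer(tr$feature), left = as.integer(tr$left),
         right = as.integer(tr$right), leaf_of = as.integer(tr$leaf_of),
         leaves = as.matrix(tr$leaves))
  })
  structure(list(trees = trees, inbag = as.matrix(obj$inbag),
                 term_order = obj$term_order, n = obj$n,
                 params = obj$params),
            class = "hmc_forest")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

binarize <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  if (any(is.na(X)) || any(X != 0L & X != 1L))
    stop("feature matrix must be binary 0/1")
  X
}
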