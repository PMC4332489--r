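# Shared fixtures: memoized synthetic worlds and independent oracles.
# Worlds are generated once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# small clean world: separable modules, complete annotation
clean_world <- function() memoize("clean_world", function() {
  simulate_world(G = 30, M = 5, F_per_module = 12, flip_noise = 0, rho = 1,
                 D = 2, B = 3, seed = 7)
})

# tiny noisy world for fast experiment-driver tests
tiny_world <- function() memoize("tiny_world", function() {
  simulate_world(G = 20, M = 4, F_per_module = 8, flip_noise = 0.05,
                 rho = 0.8, D = 2, B = 2, seed = 11)
})

# benchmark world at the default generator settings
benchmark_world <- function() memoize("benchmark_world", function() {
  simulate_world(seed = 42)
})

# benchmark world extended with a 31-genome strain block (base + 30 copies)
strain_world <- function() memoize("strain_world", function() {
  add_strain_block(benchmark_world(), "s001", n_strains = 30,
                   strain_flip = 0.02, seed = 9)
})

# hand-built ontology: chain T:3 -> T:2 -> T:1 plus a diamond leaf T:4
chain_dag <- function() {
  parse_obo(c("[Term]", "id: T:1", "name: root",
              "[Term]", "id: T:2", "is_a: T:1",
              "[Term]", "id: T:3", "is_a: T:2",
              "[Term]", "id: T:4", "is_a: T:2", "is_a: T:3"))
}

# --- independent oracles -------------------------------------------------

# brute-force hierarchy-weighted variance (double loop, no shared code)
oracle_weighted_variance <- function(V, w) {
  n <- nrow(V)
  vbar <- colMeans(V)
  total <- 0
  for (i in seq_len(n))
    for (c in seq_len(ncol(V)))
      total <- total + w[c] * (V[i, c] - vbar[c])^2
  total / n
}

# exhaustive best split: evaluate every feature with the oracle variance
oracle_best_split <- function(X, V, w, min_leaf = 1) {
  n <- nrow(X)
  parent <- oracle_weighted_variance(V, w)
  best <- list(feature = NA_integer_, gain = 0)
  for (f in seq_len(ncol(X))) {
    s1 <- X[, f] == 1
    n1 <- sum(s1); n0 <- n - n1
    if (n1 < min_leaf || n0 < min_leaf) next
    child <- (n0 / n) * oracle_weighted_variance(V[!s1, , drop = FALSE], w) +
             (n1 / n) * oracle_weighted_variance(V[s1, , drop = FALSE], w)
    gain <- parent - child
    if (gain > best$gain + 1e-12) best <- list(feature = f, gain = gain)
  }
  if (is.na(best$feature)) NULL else best
}

# independent PR curve + trapezoid area: per-threshold confusion counts by
# explicit comparison, area via pracma::trapz with the same recall-0 anchor
oracle_auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    called <- scores >= th[i]
    tp <- sum(called & labels == 1L)
    fp <- sum(called & labels == 0L)
    fn <- sum(!called & labels == 1L)
    prec[i] <- tp / (tp + fp)
    rec[i] <- tp / (tp + fn)
  }
  pracma::trapz(c(0, rec), c(prec[1], prec))
}

# replay a compiled tree's routing in plain R
r_traverse_leaf <- function(tree, x) {
  node <- 1L
  while (tree$feature[node] >= 0L) {
    node <- if (x[tree$feature[node] + 1L] == 1L)
      tree$right[node] + 1L else tree$left[node] + 1L
  }
  tree$leaves[tree$leaf_of[node] + 1L, ]
}

r_forest_predict <- function(forest, X, oob = FALSE) {
  t(vapply(seq_len(nrow(X)), function(i) {
    use <- if (oob) which(forest$inbag[i, ] == 0L) else seq_along(forest$trees)
    if (length(use) == 0L) return(rep(NA_real_, length(forest$term_order)))
    rowMeans(vapply(use, function(t)
      r_traverse_leaf(forest$trees[[t]], X[i, ]),
      numeric(length(forest$term_order))))
  }, numeric(length(forest$term_order))))
}
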