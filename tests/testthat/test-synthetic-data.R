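test_that("simulated species trees are binary, ultrametric and unit-height", {
  sp <- simulate_species_tree(4, seed = 3)
  expect_equal(length(sp$tree$tip.label), 4L)
  expect_equal(sp$tree$Nnode, 3L)

  expect_equal(diag(sp$distances), setNames(rep(0, 4), rownames(sp$distances)))
  expect_equal(sp$distances, t(sp$distances))

  depths <- ape::node.depth.edgelength(sp$tree)[1:4]
  expect_equal(depths, rep(1, 4), tolerance = 1e-9)

  # bit-reproducible per seed
  sp2 <- simulate_species_tree(4, seed = 3)
  expect_identical(ape::write.tree(sp$tree), ape::write.tree(sp2$tree))
})

test_that("module simulation realizes co-dependent loss with analytic rates", {
  sp <- simulate_species_tree(12, seed = 5)

  none <- simulate_modules(sp$tree, M = 3, F_per_module = 4, loss_rate = 0,
                           flip_noise = 0, seed = 1)
  expect_true(all(none$profiles == 1L))

  clean <- simulate_modules(sp$tree, M = 4, F_per_module = 5, loss_rate = 1,
                            flip_noise = 0, seed = 2)
  for (m in unique(clean$module_of)) {
    fam <- names(clean$module_of)[clean$module_of == m]
    expect_true(all(apply(clean$profiles[fam, , drop = FALSE], 2,
                          function(col) length(unique(col)) == 1L)))
  }

  # per-branch loss fraction at lambda * t = 0.2: star-like tree with all
  # terminal branches 0.2 and zero internal branches
  star <- ape::read.tree(text = "((a:0.2,b:0.2):0,(c:0.2,d:0.2):0);")
  sim <- simulate_modules(star, M = 1000, F_per_module = 1, loss_rate = 1,
                          flip_noise = 0, seed = 4)
  # families that lost every tip are dropped from the matrix, so absent
  # cells = dropped families * 4 + zeros among kept rows
  present_cells <- sum(sim$profiles)
  frac_lost <- (1000 * 4 - present_cells) / (1000 * 4)
  expect_lt(abs(frac_lost - (1 - exp(-0.2))), 0.02)

  # expected profile density decreases in the loss rate
  dens <- vapply(c(0.2, 0.7, 1.5), function(lam) {
    mean(simulate_modules(sp$tree, 50, 2, lam, 0, seed = 6)$profiles)
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})

test_that("simulated ontologies are balanced and module mapping is injective", {
  star <- simulate_ontology(M = 5, D = 1, B = 5, seed = 1)
  expect_equal(length(star$dag$ids), 6L)
  expect_true(all(vapply(star$dag$parents[star$dag$ids != "T:000000"],
                         identical, TRUE, y = "T:000000")))

  ont <- simulate_ontology(M = 9, D = 2, B = 3, seed = 2)
  tw <- hierarchy_weights(ont$dag, 0.75)
  expect_equal(sum(tw$depth == 2L), 9L)
  expect_equal(anyDuplicated(ont$module_to_term), 0L)
  expect_true(all(tw$depth[ont$module_to_term] == 2L))

  expect_error(simulate_ontology(M = 9, D = 1, B = 2, seed = 1), "not enough")
})

test_that("annotation completeness rho thins genes binomially", {
  big <- simulate_world(G = 100, M = 20, F_per_module = 10, flip_noise = 0,
                        rho = 1, D = 2, B = 5, seed = 13)
  n_genes <- nrow(unique(big$groups[c("gene_id", "group_id")]))
  expect_gt(n_genes, 10000)
  expect_equal(nrow(big$annotations), n_genes)  # rho = 1: every gene

  ann6 <- simulate_annotations(big$groups, big$module_of, big$module_to_term,
                               rho = 0.6, seed = 21)
  expect_lt(abs(nrow(ann6) / n_genes - 0.6), 0.01)
  expect_equal(nrow(simulate_annotations(big$groups, big$module_of,
                                         big$module_to_term, rho = 0,
                                         seed = 3)), 0L)
})

test_that("worlds are reproducible and truth is propagation-closed", {
  w1 <- tiny_world()
  w2 <- simulate_world(G = 20, M = 4, F_per_module = 8, flip_noise = 0.05,
                       rho = 0.8, D = 2, B = 2, seed = 11)
  expect_identical(w1$groups, w2$groups)
  expect_identical(w1$annotations, w2$annotations)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))

  for (g in names(w1$truth)[1:5])
    expect_identical(propagate_terms(w1$truth[[g]], w1$dag), w1$truth[[g]])

  # annotations are a rho-thinned restriction of the truth's leaf terms
  leaf <- w1$module_to_term[w1$module_of[w1$groups$group_id[
    match(w1$annotations$gene_id, w1$groups$gene_id)]]]
  expect_true(all(w1$annotations$term_id == unname(leaf)))
})

test_that("strain blocks append near-identical genome columns", {
  w <- tiny_world()
  ws0 <- add_strain_block(w, "s001", n_strains = 3, strain_flip = 0,
                          seed = 2)
  for (id in ws0$strains$ids)
    expect_identical(ws0$true_profiles[, id], ws0$true_profiles[, "s001"])

  ws <- add_strain_block(w, "s001", n_strains = 31, strain_flip = 0.02,
                         seed = 2)
  expect_equal(length(ws$genome_ids), length(w$genome_ids) + 31L)
  expect_equal(length(ws$tree$tip.label), length(w$tree$tip.label) + 31L)

  d <- ws$distances
  non_strain <- setdiff(w$genome_ids, "s001")
  expect_true(max(d["s001", ws$strains$ids]) < min(d["s001", non_strain]))
  expect_error(add_strain_block(w, "sXXX", 2), "unknown base")
})

test_that("write_world emits a consistent standard-format bundle", {
  w <- tiny_world()
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))

  groups <- read_group_table(paths[["groups"]])
  expect_equal(groups, w$groups, ignore_attr = TRUE)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(w$annotations))
  dag <- parse_obo(paths[["ontology"]])
  expect_setequal(dag$ids, w$dag$ids)
  d <- read_phylip_square(paths[["distances"]])
  expect_equal(d[rownames(w$distances), colnames(w$distances)], w$distances,
               tolerance = 1e-6)
  tr <- ape::read.tree(paths[["tree"]])
  expect_setequal(tr$tip.label, w$genome_ids)

  # profiles file matches a rebuild from the group table
  prof <- utils::read.delim(paths[["profiles"]], check.names = FALSE)
  m <- as.matrix(prof[, -1])
  rownames(m) <- prof$group_id
  rebuilt <- build_profiles(w$groups, colnames(m))
  expect_equal(m[rownames(rebuilt), ], rebuilt, ignore_attr = TRUE)
})
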