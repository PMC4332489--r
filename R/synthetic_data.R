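# Ground-truth world generator: a species tree, co-evolving gene-family
# modules gained/lost along it, a term hierarchy, and incomplete
# annotations. Emulates the statistical structure of orthology-database +
# annotation-database inputs so the whole pipeline is testable with known
# truth.

# deterministic sub-seed derivation (kept within 32-bit signed range)
sub_seed <- function(seed, i) (as.numeric(seed) * 1000003 + i) %% 2147483629

#' Simulate an ultrametric species tree and its distance matrix
#'
#' Pure-birth (Yule) tree with `G` tips, rescaled to unit root-to-tip
#' height. Tips are labelled `s001`, `s002`, ... and internal nodes
#' `n001`, ... so clades can be addressed by label. The patristic distance
#' matrix is returned alongside, ordered by tip label.
#'
#' @param G Number of genomes (tips), at least 4.
#' @param seed Integer seed.
#' @return List with `tree` (an `ape::phylo`) and `distances` (square
#'   matrix).
#' @export
simulate_species_tree <- function(G, seed = 1) {
  stopifnot(G >= 4)
  tree <- with_seed(seed, ape::rphylo(G, birth = 1, death = 0))
  tree$tip.label <- sprintf("s%03d", seq_len(G))
  tree$node.label <- sprintf("n%03d", seq_len(tree$Nnode))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(G)])
  tree$edge.length <- tree$edge.length / height
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  list(tree = tree, distances = d[ord, ord])
}

#' Simulate co-evolving gene-family modules on a species tree
#'
#' Each module draws one presence/absence pattern: present at the root and
#' lost irreversibly along each branch with probability
#' `1 - exp(-loss_rate * branch_length)`. Each of the module's
#' `families_per_module` gene families copies the module pattern and then
#' flips every cell independently with probability `flip_noise`, so
#' families within a module have correlated (co-dependent) profiles.
#' Every present (family, genome) cell yields `genes_per_cell` member
#' gene(s); families left with no presence anywhere are dropped.
#'
#' @param tree Species tree from [simulate_species_tree()].
#' @param M Number of modules.
#' @param F_per_module Families (orthology groups) per module.
#' @param loss_rate Loss rate per unit branch length (lambda >= 0).
#' @param flip_noise Per-cell flip probability epsilon in \[0, 0.5).
#' @param seed Integer seed.
#' @param genes_per_cell Genes per present cell (in-paralogs); default 1.
#' @return List with `groups` (membership `data.frame`), `profiles`
#'   (binary matrix, groups x genomes in tip-label order) and `module_of`
#'   (named character vector group -> module id).
#' @export
simulate_modules <- function(tree, M, F_per_module, loss_rate,
                             flip_noise = 0, seed = 1, genes_per_cell = 1) {
  stopifnot(loss_rate >= 0, flip_noise >= 0, flip_noise < 0.5,
            M >= 1, F_per_module >= 1)
  tree <- ape::reorder.phylo(tree, "cladewise")
  G <- length(tree$tip.label)
  genomes <- sort(tree$tip.label)
  n_edge <- nrow(tree$edge)
  surv_p <- exp(-loss_rate * tree$edge.length)

  sim <- with_seed(sub_seed(seed, 1), {
    patterns <- matrix(0L, nrow = M, ncol = G)
    colnames(patterns) <- tree$tip.label
    state <- integer(G + tree$Nnode)
    for (m in seq_len(M)) {
      state[] <- 0L
      state[G + 1L] <- 1L  # root
      keep <- stats::runif(n_edge) < surv_p
      for (e in seq_len(n_edge)) {
        state[tree$edge[e, 2L]] <-
          if (state[tree$edge[e, 1L]] == 1L && keep[e]) 1L else 0L
      }
      patterns[m, ] <- state[seq_len(G)]
    }
    patterns <- patterns[, genomes, drop = FALSE]
    n_fam <- M * F_per_module
    flips <- matrix(stats::runif(n_fam * G) < flip_noise, nrow = n_fam)
    list(patterns = patterns, flips = flips)
  })

  fam_module <- rep(seq_len(M), each = F_per_module)
  fam_ids <- sprintf("m%02d_f%02d", fam_module,
                     rep(seq_len(F_per_module), times = M))
  profiles <- sim$patterns[fam_module, , drop = FALSE]
  profiles <- abs(profiles - sim$flips * 1L)  # XOR with the noise mask
  storage.mode(profiles) <- "integer"
  rownames(profiles) <- fam_ids

  nonempty <- rowSums(profiles) > 0L
  profiles <- profiles[nonempty, , drop = FALSE]
  fam_module <- fam_module[nonempty]

  cells <- which(profiles == 1L, arr.ind = TRUE)
  groups <- data.frame(
    group_id = rownames(profiles)[cells[, 1L]],
    species_id = colnames(profiles)[cells[, 2L]],
    stringsAsFactors = FALSE
  )
  groups <- groups[rep(seq_len(nrow(groups)), each = genes_per_cell), ]
  copy <- if (genes_per_cell > 1)
    paste0("_", rep(seq_len(genes_per_cell), times = nrow(cells))) else ""
  groups$gene_id <- paste0(groups$group_id, "_", groups$species_id, copy)
  groups <- groups[order(groups$group_id, groups$species_id, groups$gene_id), ]
  rownames(groups) <- NULL

  module_of <- stats::setNames(sprintf("m%02d", fam_module), rownames(profiles))
  list(groups = groups, profiles = profiles[unique(groups$group_id), , drop = FALSE],
       module_of = module_of)
}

#' Simulate a balanced tree-shaped term hierarchy
#'
#' Builds a rooted ontology of depth `D` with branching factor `B`
#' (`B^D` leaves) and maps each module to a distinct leaf term.
#'
#' @param M Number of modules to map (needs `B^D >= M`).
#' @param D Ontology depth.
#' @param B Branching factor.
#' @param seed Integer seed (controls which leaves are used).
#' @return List with `dag` (an `ontology_dag`) and `module_to_term`
#'   (named character vector, module id -> leaf term id).
#' @export
simulate_ontology <- function(M, D, B, seed = 1) {
  if (B^D < M) stop("B^D = ", B^D, " leaves are not enough for ", M, " modules")
  ids <- "T:000000"
  term_names <- stats::setNames("root", ids)
  parents <- list("T:000000" = character(0))
  level <- ids
  for (d in seq_len(D)) {
    nxt <- character(0)
    idx <- 0L
    for (p in level) {
      for (b in seq_len(B)) {
        idx <- idx + 1L
        id <- sprintf("T:%d%05d", d, idx)
        ids <- c(ids, id)
        term_names[id] <- sprintf("level-%d term %d", d, idx)
        parents[[id]] <- p
        nxt <- c(nxt, id)
      }
    }
    level <- nxt
  }
  dag <- structure(list(ids = ids, names = term_names, parents = parents,
                        roots = "T:000000"),
                   class = "ontology_dag")
  leaves <- with_seed(sub_seed(seed, 2), sample(level, M))
  list(dag = dag,
       module_to_term = stats::setNames(leaves, sprintf("m%02d", seq_len(M))))
}

#' Simulate an incomplete annotation table
#'
#' Every gene's true label is the leaf term of its family's module; each
#' gene's annotation is observed with probability `rho` (annotation
#' completeness), independently, realizing the Open World Assumption:
#' unobserved annotations are missing, not false.
#'
#' @param groups Group membership `data.frame`.
#' @param module_of Named vector group -> module.
#' @param module_to_term Named vector module -> leaf term.
#' @param rho Observation probability in \[0, 1\].
#' @param seed Integer seed.
#' @param evidence_code Code attached to observed rows; default `"IDA"`.
#' @return Annotation `data.frame` (`gene_id`, `term_id`, `evidence_code`).
#' @export
simulate_annotations <- function(groups, module_of, module_to_term, rho,
                                 seed = 1, evidence_code = "IDA") {
  stopifnot(rho >= 0, rho <= 1)
  genes <- unique(groups[c("group_id", "gene_id")])
  term <- unname(module_to_term[module_of[genes$group_id]])
  seen <- with_seed(sub_seed(seed, 3), stats::runif(nrow(genes)) < rho)
  out <- data.frame(gene_id = genes$gene_id[seen], term_id = term[seen],
                    evidence_code = rep_len(evidence_code, sum(seen)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic world
#'
#' Chains [simulate_species_tree()], [simulate_modules()],
#' [simulate_ontology()] and [simulate_annotations()] into one ground-truth
#' bundle. Defaults are the benchmark condition: 200 genomes,
#' 40 modules of 25 families (1000 groups), loss rate `log(2)` giving ~50%
#' expected presence per cell on the unit-height tree, 5% family flip
#' noise, 60% annotation completeness, and a depth-3 branching-4 ontology.
#'
#' @param G Number of genomes.
#' @param M Number of co-evolving modules.
#' @param F_per_module Gene families per module.
#' @param loss_rate Loss rate lambda per unit branch length.
#' @param flip_noise Per-family per-cell flip probability epsilon.
#' @param rho Annotation completeness in \[0, 1\].
#' @param D,B Ontology depth and branching factor.
#' @param genes_per_cell Genes per present (family, genome) cell.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A `synthetic_world` list: `params`, `tree`, `distances`,
#'   `groups`, `true_profiles`, `dag`, `module_of`, `module_to_term`,
#'   `annotations`, `truth` (named list, group -> propagation-closed true
#'   term set) and `genome_ids`.
#' @export
simulate_world <- function(G = 200, M = 40, F_per_module = 25,
                           loss_rate = log(2), flip_noise = 0.05, rho = 0.6,
                           D = 3, B = 4, genes_per_cell = 1, seed = 1) {
  sp <- simulate_species_tree(G, seed = sub_seed(seed, 10))
  mod <- simulate_modules(sp$tree, M, F_per_module, loss_rate, flip_noise,
                          seed = sub_seed(seed, 20),
                          genes_per_cell = genes_per_cell)
  ont <- simulate_ontology(M, D, B, seed = sub_seed(seed, 30))
  ann <- simulate_annotations(mod$groups, mod$module_of, ont$module_to_term,
                              rho, seed = sub_seed(seed, 40))
  leaf_terms <- ont$module_to_term[mod$module_of]
  truth <- lapply(stats::setNames(leaf_terms, names(mod$module_of)),
                  propagate_terms, dag = ont$dag)
  structure(
    list(params = list(G = G, M = M, F_per_module = F_per_module,
                       loss_rate = loss_rate, flip_noise = flip_noise,
                       rho = rho, D = D, B = B,
                       genes_per_cell = genes_per_cell, seed = seed),
         tree = sp$tree, distances = sp$distances, groups = mod$groups,
         true_profiles = mod$profiles, dag = ont$dag,
         module_of = mod$module_of, module_to_term = ont$module_to_term,
         annotations = ann, truth = truth,
         genome_ids = colnames(mod$profiles), strains = NULL),
    class = "synthetic_world"
  )
}

#' Append a block of near-identical strain genomes
#'
#' Models many sequenced strains of one organism: `n_strains` new genome
#' columns copy `base_genome`'s presence column with per-cell flip
#' probability `strain_flip`, the tree gains a tiny star clade at the base
#' tip, and the distance matrix is extended with near-zero within-block
#' distances. New genes are annotated with the world's completeness `rho`.
#'
#' @param world A `synthetic_world`.
#' @param base_genome Genome id to clone.
#' @param n_strains Number of strain copies.
#' @param strain_flip Per-cell flip probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return The extended `synthetic_world`; the new ids are recorded in
#'   `world$strains`.
#' @export
add_strain_block <- function(world, base_genome, n_strains,
                             strain_flip = 0.02, seed = 1) {
  stopifnot(inherits(world, "synthetic_world"),
            strain_flip >= 0, strain_flip < 0.5, n_strains >= 1)
  if (!base_genome %in% world$genome_ids)
    stop("unknown base genome: ", base_genome)
  strain_ids <- sprintf("%s_strain%02d", base_genome, seq_len(n_strains))
  base_col <- world$true_profiles[, base_genome]

  new_cols <- with_seed(sub_seed(seed, 50), {
    flips <- matrix(stats::runif(length(base_col) * n_strains) < strain_flip,
                    ncol = n_strains)
    abs(matrix(base_col, ncol = n_strains, nrow = length(base_col)) - flips * 1L)
  })
  storage.mode(new_cols) <- "integer"
  colnames(new_cols) <- strain_ids
  world$true_profiles <- cbind(world$true_profiles, new_cols)

  cells <- which(new_cols == 1L, arr.ind = TRUE)
  new_groups <- data.frame(
    group_id = rownames(world$true_profiles)[cells[, 1L]],
    species_id = strain_ids[cells[, 2L]],
    stringsAsFactors = FALSE
  )
  new_groups$gene_id <- paste0(new_groups$group_id, "_", new_groups$species_id)
  world$groups <- rbind(world$groups, new_groups)

  new_ann <- simulate_annotations(new_groups, world$module_of,
                                  world$module_to_term, world$params$rho,
                                  seed = sub_seed(seed, 51))
  world$annotations <- rbind(world$annotations, new_ann)

  # tree: replace the base tip with a tiny star clade of base + strains
  eps_bl <- 1e-6
  star <- ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%g", c(base_genome, strain_ids), eps_bl),
               collapse = ","), ");"))
  tip <- which(world$tree$tip.label == base_genome)
  world$tree <- ape::bind.tree(world$tree, star, where = tip)

  d <- world$distances
  base_row <- d[base_genome, ]
  ext <- matrix(rep(base_row, n_strains), nrow = n_strains, byrow = TRUE,
                dimnames = list(strain_ids, colnames(d)))
  ext <- ext + eps_bl
  d <- rbind(cbind(d, t(ext)), cbind(ext, matrix(2 * eps_bl, n_strains, n_strains,
                                                 dimnames = list(strain_ids, strain_ids))))
  d[cbind(strain_ids, strain_ids)] <- 0
  d[base_genome, strain_ids] <- 2 * eps_bl
  d[strain_ids, base_genome] <- 2 * eps_bl
  world$distances <- d

  world$genome_ids <- c(world$genome_ids, strain_ids)
  world$strains <- list(base = base_genome, ids = strain_ids,
                        strain_flip = strain_flip)
  world
}

#' Write a synthetic world as standard-format files
#'
#' Emits `tree.nwk` (Newick), `distances.phy` (square PHYLIP),
#' `groups.tsv`, `ontology.obo`, `annotations.tsv` (GAF-like),
#' `profiles.tsv`, `truth.tsv` (group_id, term_id pairs of the closed true
#' term sets) and `params.json` into `dir`, so downstream steps can run
#' purely from files.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             distances = file.path(dir, "distances.phy"),
             groups = file.path(dir, "groups.tsv"),
             ontology = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             profiles = file.path(dir, "profiles.tsv"),
             truth = file.path(dir, "truth.tsv"),
             params = file.path(dir, "params.json"))
  ape::write.tree(world$tree, paths["tree"])
  write_phylip_square(world$distances, paths["distances"])
  utils::write.table(world$groups, paths["groups"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_obo(world$dag, paths["ontology"])
  write_annotations(world$annotations, paths["annotations"])
  write_profiles(world$true_profiles, paths["profiles"])
  truth_df <- data.frame(
    group_id = rep(names(world$truth), lengths(world$truth)),
    term_id = unlist(world$truth, use.names = FALSE))
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(world$params, paths["params"], auto_unbox = TRUE,
                       digits = NA)
  paths
}
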