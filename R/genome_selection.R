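# Genome-subset selection: random, greedy maximum phylogenetic diversity,
# clade-restricted, and fixed published lists.

#' Read a square PHYLIP distance matrix
#'
#' First line: taxon count n; then n rows of `label d1 ... dn`. The matrix
#' must be symmetric (tolerance 1e-9) with a zero diagonal.
#'
#' @param path File path.
#' @return Numeric matrix with genome ids as dimnames, in file order.
#' @export
read_phylip_square <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || n < 1L) stop("invalid taxon count on first line")
  if (length(lines) - 1L != n)
    stop("expected ", n, " matrix rows, found ", length(lines) - 1L)
  parts <- strsplit(trimws(lines[-1L]), "[[:space:]]+")
  if (any(lengths(parts) != n + 1L)) stop("each row needs a label and ", n, " values")
  labels <- vapply(parts, `[[`, "", 1L)
  d <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(n)))
  if (anyNA(d)) stop("non-numeric distance value")
  dimnames(d) <- list(labels, labels)
  validate_distance_matrix(d)
  d
}

validate_distance_matrix <- function(d) {
  if (any(abs(diag(d)) > 1e-9)) stop("distance matrix diagonal must be zero")
  if (any(abs(d - t(d)) > 1e-9)) stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < -1e-9)) stop("distances must be finite and non-negative")
  invisible(d)
}

#' Write a square PHYLIP distance matrix
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @param digits Significant digits written; default 10.
#' @export
write_phylip_square <- function(d, path, digits = 10) {
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste(rownames(d)[i], paste(format(d[i, ], digits = digits, trim = TRUE),
                                collapse = " "))
  }, "")
  writeLines(c(as.character(nrow(d)), rows), path)
  invisible(path)
}

selection_result <- function(strategy, genomes, seed = NULL, replicate = NULL,
                             extra = list()) {
  stopifnot(!anyDuplicated(genomes))
  structure(c(list(strategy = strategy, genomes = genomes, seed = seed,
                   replicate = replicate), extra),
            class = "genome_selection")
}

#' Random genome subset
#'
#' @param genome_ids Available genome ids.
#' @param k Subset size.
#' @param seed Integer seed (one replicate per seed; drivers run several
#'   seeds and average downstream).
#' @param replicate Optional replicate index recorded in the result.
#' @return A `genome_selection` with `strategy = "random"`.
#' @export
select_random <- function(genome_ids, k, seed, replicate = NULL) {
  n <- length(genome_ids)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  picked <- with_seed(seed, sample(genome_ids, k))
  selection_result("random", picked, seed = seed, replicate = replicate)
}

#' Greedy maximum-phylogenetic-diversity genome subset
#'
#' Repeatedly finds the two closest genomes in the distance matrix and
#' excludes the one with fewer annotations, until `k` genomes remain.
#' Deterministic tie rules: among equal minimal distances the
#' lexicographically smallest (id1, id2) pair is taken; with equal
#' annotation counts the lexicographically larger id is dropped. The full
#' matrix is rescanned each iteration.
#'
#' @param dist Square distance matrix with genome-id dimnames.
#' @param ann_counts Named numeric vector, annotation count per genome
#'   (must cover all genomes in `dist`).
#' @param k Number of genomes to keep.
#' @return A `genome_selection` with `strategy = "maxdiv"` (genomes in the
#'   original matrix order).
#' @export
select_max_diversity <- function(dist, ann_counts, k) {
  validate_distance_matrix(dist)
  ids <- rownames(dist)
  if (k < 1 || k > length(ids)) stop("k must be in [1, ", length(ids), "]")
  missing <- setdiff(ids, names(ann_counts))
  if (length(missing) > 0L)
    stop("ann_counts missing genome(s): ", paste(missing, collapse = ", "))
  alive <- ids
  while (length(alive) > k) {
    d <- dist[alive, alive]
    diag(d) <- Inf
    # lexicographically smallest closest pair: scan in sorted-id order
    o <- order(rownames(d))
    d <- d[o, o]
    m <- min(d)
    hit <- which(d == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    a <- rownames(d)[hit[1L, 1L]]
    b <- rownames(d)[hit[1L, 2L]]
    drop <- if (ann_counts[a] < ann_counts[b]) a
            else if (ann_counts[b] < ann_counts[a]) b
            else max(a, b)
    alive <- setdiff(alive, drop)
  }
  selection_result("maxdiv", alive)
}

#' Genomes forming a named clade of a species tree
#'
#' @param tree An `ape::phylo` tree or a Newick file path/string.
#' @param clade Either the label of an internal node, a tip label (giving a
#'   single-genome "clade"), or an internal node number.
#' @return A `genome_selection` with `strategy = "clade"` containing all
#'   descendant tips.
#' @export
select_clade <- function(tree, clade) {
  tree <- as_phylo(tree)
  n_tip <- length(tree$tip.label)
  if (is.numeric(clade)) {
    node <- as.integer(clade)
    if (node < 1L || node > n_tip + tree$Nnode) stop("node number out of range")
  } else if (clade %in% tree$tip.label) {
    return(selection_result("clade", clade, extra = list(clade = clade)))
  } else {
    hits <- which(!is.na(tree$node.label) & tree$node.label == clade)
    if (length(hits) != 1L)
      stop("clade label '", clade, "' does not resolve to exactly one internal node; ",
           "available: ", paste(utils::head(stats::na.omit(tree$node.label), 10L),
                                collapse = ", "))
    node <- n_tip + hits
  }
  tips <- if (node <= n_tip) tree$tip.label[node]
          else ape::extract.clade(tree, node)$tip.label
  selection_result("clade", tips, extra = list(clade = clade))
}

#' Load a fixed genome list, reporting ids missing from the data
#'
#' One genome id per line; duplicates are removed with a warning, ids not
#' present in `available` are dropped and recorded in the result's
#' `missing` field (mirroring the bookkeeping needed when published lists
#' don't fully overlap a database release).
#'
#' @param path Text file, one id per line.
#' @param available Character vector of genomes present in the data.
#' @return A `genome_selection` with `strategy = "list"` and a `missing`
#'   field.
#' @export
load_genome_list <- function(path, available) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning("duplicate ids in genome list removed")
    ids <- unique(ids)
  }
  missing <- setdiff(ids, available)
  kept <- ids[ids %in% available]
  if (length(kept) == 0L) stop("no listed genome is available")
  selection_result("list", kept, extra = list(missing = missing))
}

#' Write a genome selection as id list + JSON sidecar
#'
#' @param sel A `genome_selection`.
#' @param path Output path for the id list (one per line); the sidecar is
#'   written to `paste0(path, ".json")`.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "genome_selection"))
  writeLines(sel$genomes, path)
  meta <- sel[setdiff(names(sel), "genomes")]
  meta$k <- length(sel$genomes)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Patristic distances from a Newick tree
#'
#' @param tree An `ape::phylo`, Newick string, or file path.
#' @return Square distance matrix (tip order).
#' @export
tree_distances <- function(tree) {
  d <- ape::cophenetic.phylo(as_phylo(tree))
  validate_distance_matrix(d)
  d
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (length(tree) == 1L && !grepl("\\(", tree) && file.exists(tree))
    return(ape::read.tree(tree))
  ape::read.tree(text = tree)
}
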