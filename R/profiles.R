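# Orthology-group tables, annotation tables and binary profile matrices.

#' Default experimental evidence-code whitelist
#'
#' Annotations backed by direct experimental evidence: EXP, IMP, IGI, IPI,
#' IEP and IDA.
#' @export
experimental_evidence_codes <- c("EXP", "IMP", "IGI", "IPI", "IEP", "IDA")

#' Read an orthology-group membership table
#'
#' Expects a TSV with header `group_id species_id gene_id`. Duplicate
#' (group, species, gene) rows collapse to one.
#'
#' @param path TSV file path.
#' @return A `data.frame` with columns `group_id`, `species_id`, `gene_id`.
#' @export
read_group_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("group_id", "species_id", "gene_id")
  if (!all(need %in% names(df)))
    stop("group table must have columns: ", paste(need, collapse = ", "))
  unique(df[need])
}

#' Read a GAF-like annotation table with evidence filtering
#'
#' Accepts either a 3-column TSV (`gene_id`, `term_id`, `evidence_code`,
#' with or without that header) or a full 17-column GAF 2.x file (columns
#' 2, 5 and 7 are used; `!`-comment lines skipped). Rows whose evidence
#' code is not in the whitelist are dropped, duplicates collapsed, and
#' malformed rows skipped with a warning.
#'
#' @param path File path.
#' @param evidence_whitelist Character vector of accepted evidence codes.
#' @return A `data.frame` with columns `gene_id`, `term_id`,
#'   `evidence_code`, carrying attributes `n_kept` and `n_dropped`
#'   (rows removed by the evidence filter).
#' @export
read_annotations <- function(path, evidence_whitelist = experimental_evidence_codes) {
  if (length(evidence_whitelist) == 0L)
    stop("evidence whitelist must be non-empty")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  malformed <- n_col < 3L
  if (any(malformed)) {
    warning(sum(malformed), " malformed annotation row(s) skipped")
    fields <- fields[!malformed]
    n_col <- n_col[!malformed]
  }
  pick <- function(f, n) if (n >= 15L) f[c(2L, 5L, 7L)] else f[1:3]
  mat <- t(mapply(pick, fields, n_col))
  df <- data.frame(gene_id = mat[, 1L], term_id = mat[, 2L],
                   evidence_code = mat[, 3L], stringsAsFactors = FALSE)
  # tolerate a 3-column header row
  if (nrow(df) > 0L && identical(tolower(df$gene_id[1L]), "gene_id"))
    df <- df[-1L, , drop = FALSE]
  n0 <- nrow(unique(df))
  df <- df[df$evidence_code %in% evidence_whitelist, , drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  if (nrow(df) == 0L) warning("no annotations passed the evidence filter")
  attr(df, "n_kept") <- nrow(df)
  attr(df, "n_dropped") <- n0 - nrow(df)
  df
}

#' Write an annotation table as 3-column TSV
#' @param ann Annotation `data.frame`.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann[c("gene_id", "term_id", "evidence_code")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Build a binary phylogenetic profile matrix
#'
#' One row per orthology group, one column per genome; cell (g, s) is 1
#' iff group g has at least one member gene in species s. Species present
#' in the group table but absent from `genome_ids` are projected out, which
#' is how genome-selection experiments restrict profiles to a subset of
#' columns. Row order is the first-appearance order of groups in the table.
#'
#' @param groups Group membership `data.frame`
#'   (`group_id`, `species_id`, `gene_id`).
#' @param genome_ids Ordered character vector of genome (species) ids.
#' @return Integer matrix with `rownames` = group ids and
#'   `colnames` = `genome_ids`.
#' @export
build_profiles <- function(groups, genome_ids) {
  if (length(genome_ids) == 0L) stop("genome list must be non-empty")
  if (anyDuplicated(genome_ids)) stop("duplicate genome ids")
  gids <- unique(groups$group_id)
  m <- matrix(0L, nrow = length(gids), ncol = length(genome_ids),
              dimnames = list(gids, genome_ids))
  keep <- groups$species_id %in% genome_ids
  if (any(keep))
    m[cbind(match(groups$group_id[keep], gids),
            match(groups$species_id[keep], genome_ids))] <- 1L
  m
}

#' Write a profile matrix as TSV (first column group_id)
#' @param profiles Binary matrix from [build_profiles()].
#' @param path Output path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(group_id = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Assign terms to orthology groups by the at-least-half rule
#'
#' Each gene's annotation set is first (optionally) closed under is_a
#' ancestors; a term is then assigned to a group when at least
#' `half_fraction` of ALL group members (annotated or not) carry it.
#' Annotation rows whose term is absent from the DAG are dropped with a
#' warning.
#'
#' @param groups Group membership `data.frame`.
#' @param ann Annotation `data.frame` (`gene_id`, `term_id`, ...).
#' @param dag An `ontology_dag`.
#' @param half_fraction Required fraction of members, in (0, 1]; default 0.5
#'   ("at least half").
#' @param propagate If `TRUE` (default), per-gene term sets are closed under
#'   ancestors before counting (true-path rule).
#' @return A list of class `group_annotations`: `terms` (named list,
#'   group id -> sorted character vector of assigned terms) and `support`
#'   (named integer vector, term -> number of groups carrying it).
#' @export
annotate_groups <- function(groups, ann, dag, half_fraction = 0.5,
                            propagate = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!is.numeric(half_fraction) || half_fraction <= 0 || half_fraction > 1)
    stop("half_fraction must be in (0, 1]")
  bad <- !(ann$term_id %in% dag$ids)
  if (any(bad)) {
    warning(sum(bad), " annotation row(s) with term ids absent from the ontology dropped")
    ann <- ann[!bad, , drop = FALSE]
  }
  gids <- unique(groups$group_id)

  # per-gene propagated term sets, computed once per distinct raw term set
  gene_terms <- split(ann$term_id, ann$gene_id)
  if (propagate) {
    gene_terms <- lapply(gene_terms, function(ts) propagate_terms(unique(ts), dag))
  } else {
    gene_terms <- lapply(gene_terms, function(ts) sort(unique(ts)))
  }

  member_key <- paste(groups$species_id, groups$gene_id)
  if (anyDuplicated(paste(groups$group_id, member_key)))
    groups <- groups[!duplicated(paste(groups$group_id, member_key)), , drop = FALSE]

  genes_by_group <- split(groups$gene_id, groups$group_id)
  terms_by_group <- lapply(gids, function(g) {
    members <- genes_by_group[[g]]
    n <- length(members)
    tl <- gene_terms[intersect(members, names(gene_terms))]
    if (length(tl) == 0L) return(character(0))
    counts <- table(unlist(tl, use.names = FALSE))
    sort(names(counts)[counts >= half_fraction * n])
  })
  names(terms_by_group) <- gids

  support_tab <- table(unlist(terms_by_group, use.names = FALSE))
  support <- stats::setNames(as.integer(support_tab), names(support_tab))
  structure(list(terms = terms_by_group, support = support),
            class = "group_annotations")
}

#' Terms supported by at least `min_support` profiles
#'
#' @param ga A `group_annotations` object.
#' @param min_support Minimum number of groups (profiles) a term must be
#'   assigned to; default 50.
#' @return Sorted character vector of term ids.
#' @export
filter_terms <- function(ga, min_support = 50) {
  stopifnot(inherits(ga, "group_annotations"), min_support >= 1)
  sort(names(ga$support)[ga$support >= min_support])
}

#' Subsample annotation rows (nested, seed-deterministic)
#'
#' Keeps `round(fraction * nrow(ann))` rows. Sampling is nested: a single
#' permutation of the rows is drawn from `seed` and a prefix of it is kept,
#' so for a fixed seed the rows retained at fraction f are a subset of those
#' retained at any f' > f. Sweeps over fractions are therefore monotone in
#' data content by construction.
#'
#' @param ann Annotation `data.frame`.
#' @param fraction Fraction of rows to keep, in \[0, 1\].
#' @param seed Integer seed.
#' @return Subsetted annotation `data.frame` (original row order preserved).
#' @export
subsample_annotations <- function(ann, fraction, seed) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  n <- nrow(ann)
  k <- round(fraction * n)
  if (k == n) return(ann)
  perm <- with_seed(seed, sample.int(n))
  keep <- sort(perm[seq_len(k)])
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict annotations to well-annotated genes
#'
#' Keeps only rows whose gene carries at least `min_terms` distinct raw
#' (pre-propagation) annotated terms — a proxy for comprehensively
#' annotated gene products under the Open World Assumption.
#'
#' @param ann Annotation `data.frame`.
#' @param min_terms Minimum distinct terms per gene; default 5.
#' @return Subsetted annotation `data.frame`.
#' @export
well_annotated_genes <- function(ann, min_terms = 5) {
  stopifnot(min_terms >= 1)
  uniq <- unique(ann[c("gene_id", "term_id")])
  counts <- table(uniq$gene_id)
  keep_genes <- names(counts)[counts >= min_terms]
  out <- ann[ann$gene_id %in% keep_genes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distinct raw annotation count per genome
#'
#' Counts, for each genome, the distinct (gene, term) annotation pairs over
#' the genes that genome contributes to the group table. Used as the
#' annotation-richness score when the maximum-diversity genome selection
#' must discard one of a closest pair.
#'
#' @param groups Group membership `data.frame`.
#' @param ann Annotation `data.frame`.
#' @param genome_ids Genomes to score (default: all in `groups`).
#' @return Named integer vector genome -> count (0 for unannotated genomes).
#' @export
genome_annotation_counts <- function(groups, ann,
                                     genome_ids = unique(groups$species_id)) {
  uniq <- unique(ann[c("gene_id", "term_id")])
  per_gene <- table(uniq$gene_id)
  gene_species <- unique(groups[c("species_id", "gene_id")])
  counts <- stats::setNames(integer(length(genome_ids)), genome_ids)
  gene_species <- gene_species[gene_species$species_id %in% genome_ids, ]
  hit <- per_gene[gene_species$gene_id]
  hit[is.na(hit)] <- 0L
  agg <- tapply(as.integer(hit), gene_species$species_id, sum)
  counts[names(agg)] <- as.integer(agg)
  counts
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
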