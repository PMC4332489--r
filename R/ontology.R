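#' @useDynLib phyloprof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parse a minimal OBO document into an ontology DAG
#'
#' Reads `[Term]` stanzas and honours only the `id`, `name`, `is_a` and
#' `is_obsolete` tags; every other tag is ignored. Obsolete terms are
#' dropped entirely. `is_a` lines become child-to-parent edges and the
#' resulting graph is checked for acyclicity.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines
#'   (anything containing a newline or a `[Term]` stanza is treated as
#'   document text rather than a path).
#' @return An object of class `ontology_dag`: a list with elements
#'   `ids` (character vector of term ids), `names` (named character vector),
#'   `parents` (named list, child id -> character vector of parent ids) and
#'   `roots` (ids with no parent).
#' @examples
#' dag <- parse_obo(c("[Term]", "id: T:1", "[Term]", "id: T:2", "is_a: T:1"))
#' dag$roots
#' @export
parse_obo <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && !grepl("^\\[", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)

  # split into stanzas; only [Term] stanzas matter
  stanza_starts <- grep("^\\[", lines)
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found")
  bounds <- c(stanza_starts, length(lines) + 1L)

  ids <- character(0)
  term_names <- character(0)
  parents <- list()

  for (i in seq_along(stanza_starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    if (block[1L] != "[Term]") next
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE))
    if (length(id) == 0L || !nzchar(id[1L])) stop("[Term] stanza without id")
    id <- id[1L]
    if (any(grepl("^is_obsolete: *true", block))) next
    if (id %in% ids) stop("duplicate term id: ", id)
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE))
    isa <- sub("^is_a: *", "", grep("^is_a:", block, value = TRUE))
    isa <- sub(" *!.*$", "", isa)  # strip trailing "! name" comments
    ids <- c(ids, id)
    term_names[id] <- if (length(nm)) nm[1L] else id
    parents[[id]] <- unique(isa)
  }
  if (length(ids) == 0L) stop("no non-obsolete terms in document")

  all_parents <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(all_parents, ids)
  if (length(unknown) > 0L)
    stop("is_a references unknown term id(s): ", paste(unknown, collapse = ", "))

  dag <- structure(
    list(ids = ids, names = term_names, parents = parents,
         roots = ids[vapply(parents[ids], length, 1L) == 0L]),
    class = "ontology_dag"
  )
  assert_acyclic(dag)
  if (length(dag$roots) == 0L) stop("ontology has no root term")
  dag
}

# Kahn topological sort; errors on a cycle, naming one offending edge.
# Returns ids in an order where parents precede children.
topo_sort <- function(dag) {
  indeg <- vapply(dag$parents[dag$ids], length, 1L)
  names(indeg) <- dag$ids
  children <- children_map(dag)
  queue <- dag$ids[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(dag$ids)) {
    bad <- setdiff(dag$ids, out)[1L]
    stop("cycle detected in ontology, involving edge ", bad, " -> ",
         dag$parents[[bad]][1L])
  }
  out
}

assert_acyclic <- function(dag) invisible(topo_sort(dag))

children_map <- function(dag) {
  children <- stats::setNames(vector("list", length(dag$ids)), dag$ids)
  for (ch in dag$ids)
    for (p in dag$parents[[ch]])
      children[[p]] <- c(children[[p]], ch)
  children
}

#' Close a term set under is_a ancestors (true-path rule)
#'
#' Returns the input terms together with every ancestor reachable through
#' `is_a` edges. Idempotent and monotone: the result is always a superset of
#' the input, and propagating twice changes nothing.
#'
#' @param terms Character vector of term ids (may be empty).
#' @param dag An `ontology_dag`.
#' @return Sorted character vector of term ids.
#' @export
propagate_terms <- function(terms, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (length(terms) == 0L) return(character(0))
  unknown <- setdiff(terms, dag$ids)
  if (length(unknown) > 0L)
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  seen <- unique(terms)
  frontier <- seen
  while (length(frontier) > 0L) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(up, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

#' Depth-decaying hierarchy weights for class-vector distances
#'
#' Assigns every term a positive weight used by the hierarchical
#' multi-label split criterion: roots get weight 1 and each other term gets
#' `w0` times the mean of its parents' weights, so weight decays
#' geometrically with depth along single-parent chains. Deeper (more
#' specific) terms therefore contribute less to the weighted class-vector
#' variance, mirroring the convention of HMC decision-tree systems.
#'
#' @param dag An `ontology_dag`.
#' @param w0 Decay factor in (0, 1]; default 0.75.
#' @return A list of class `term_weights` with elements `w0`, `weight`
#'   (named numeric over all terms) and `depth` (named integer, shortest
#'   is_a distance to a root).
#' @export
hierarchy_weights <- function(dag, w0 = 0.75) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!is.numeric(w0) || length(w0) != 1L || is.na(w0) || w0 <= 0 || w0 > 1)
    stop("w0 must be a single number in (0, 1]")
  order <- topo_sort(dag)
  weight <- stats::setNames(numeric(length(dag$ids)), dag$ids)
  depth <- stats::setNames(integer(length(dag$ids)), dag$ids)
  for (id in order) {
    ps <- dag$parents[[id]]
    if (length(ps) == 0L) {
      weight[id] <- 1
      depth[id] <- 0L
    } else {
      weight[id] <- w0 * mean(weight[ps])
      depth[id] <- min(depth[ps]) + 1L
    }
  }
  structure(list(w0 = w0, weight = weight, depth = depth),
            class = "term_weights")
}

#' Serialize an ontology DAG back to minimal OBO text
#'
#' @param dag An `ontology_dag`.
#' @param path Optional file path; if `NULL` the lines are returned.
#' @return Character vector of OBO lines (invisibly when written to file).
#' @export
write_obo <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  lines <- unlist(lapply(dag$ids, function(id) {
    c("[Term]", paste0("id: ", id), paste0("name: ", dag$names[[id]]),
      if (length(dag$parents[[id]])) paste0("is_a: ", dag$parents[[id]]),
      "")
  }), use.names = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write term depths and hierarchy weights as TSV
#'
#' Columns: `term_id`, `depth`, `weight`.
#'
#' @param tw A `term_weights` object from [hierarchy_weights()].
#' @param path Output file path.
#' @export
write_term_weights <- function(tw, path) {
  stopifnot(inherits(tw, "term_weights"))
  df <- data.frame(term_id = names(tw$weight),
                   depth = as.integer(tw$depth[names(tw$weight)]),
                   weight = unname(tw$weight),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
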