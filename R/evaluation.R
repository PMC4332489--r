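# Per-term precision-recall curves and AUPRC from OOB probabilities.

#' Precision-recall curve at the distinct score thresholds
#'
#' Thresholds are the distinct scores in descending order; at each
#' threshold an example is called positive iff its score is >= the
#' threshold, so tied scores share a single curve point. Recall is
#' non-decreasing along the curve.
#'
#' @param scores Numeric vector of per-example scores.
#' @param labels Binary (0/1 or logical) vector of the same length.
#' @return A `data.frame` of class `pr_curve` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `recall`, `precision`, or `NULL` when there are no
#'   positive labels (the term is unsupported; the caller applies the
#'   zero-AUPRC rule).
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) return(NULL)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative confusion counts at each position, collapsed to the last
  # position of each distinct score (ties share one threshold)
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- which(!duplicated(s, fromLast = TRUE))
  df <- data.frame(threshold = s[last], tp = tp[last], fp = fp[last],
                   fn = n_pos - tp[last])
  df$recall <- df$tp / n_pos
  df$precision <- df$tp / (df$tp + df$fp)
  class(df) <- c("pr_curve", "data.frame")
  df
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration over recall, prepending an anchor point at
#' recall 0 with the precision of the highest-threshold point (rather than
#' an arbitrary precision-1 anchor).
#'
#' @param curve A `pr_curve` from [pr_curve()].
#' @return Area in \[0, 1\].
#' @export
auprc <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) stop("empty PR curve")
  r <- c(0, curve$recall)
  p <- c(curve$precision[1L], curve$precision)
  sum(diff(r) * (p[-1L] + p[-length(p)]) / 2)
}

#' Per-term AUPRC with the zero rule for unsupported terms
#'
#' @param scores Per-example scores for one term.
#' @param labels Binary labels for that term.
#' @return List of class `term_auprc`: `auprc`, `n_pos`, `supported`.
#'   A term with no positive example is unsupported and scores 0.
#' @export
term_auprc <- function(scores, labels) {
  curve <- pr_curve(scores, labels)
  if (is.null(curve))
    return(structure(list(auprc = 0, n_pos = 0L, supported = FALSE),
                     class = "term_auprc"))
  structure(list(auprc = auprc(curve), n_pos = sum(as.integer(labels) == 1L),
                 supported = TRUE),
            class = "term_auprc")
}

#' Zero-fill AUPRC results over a fixed term universe
#'
#' Every term of the universe gets a value; terms without a (supported)
#' result get 0 — a model without enough data to infer annotations for a
#' term scores zero rather than being silently excluded.
#'
#' @param term_universe Character vector of term ids.
#' @param results Named list of `term_auprc` objects (or named numeric
#'   vector of AUPRC values); names must be a subset of the universe.
#' @return Named numeric vector over `term_universe`.
#' @export
zero_fill <- function(term_universe, results) {
  vals <- if (is.list(results))
    vapply(results, function(r) if (isTRUE(r$supported)) r$auprc else 0,
           numeric(1))
  else stats::setNames(as.numeric(results), names(results))
  outside <- setdiff(names(vals), term_universe)
  if (length(outside) > 0L)
    stop("result term(s) outside the universe: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  filled <- stats::setNames(numeric(length(term_universe)), term_universe)
  filled[names(vals)] <- vals
  filled
}

#' Mean AUPRC over a zero-filled term map
#'
#' @param filled Named numeric vector as returned by [zero_fill()].
#' @return Arithmetic mean.
#' @export
mean_auprc <- function(filled) {
  if (length(filled) == 0L) stop("empty AUPRC map")
  mean(filled)
}

#' Score every term of a universe from OOB predictions
#'
#' Drops zero-coverage examples, builds a per-term PR curve from the OOB
#' probabilities against the class vectors, and zero-fills over the
#' universe.
#'
#' @param oob An `oob_predictions` object.
#' @param V Class-vector matrix used at fit time (labels).
#' @param term_universe Terms to report; default all columns of `V`.
#' @return List: `auprc` (named vector over the universe, zero-filled) and
#'   `detail` (`data.frame` with term_id, n_pos, supported, auprc).
#' @export
score_terms <- function(oob, V, term_universe = colnames(V)) {
  stopifnot(inherits(oob, "oob_predictions"))
  keep <- oob$coverage > 0L
  prob <- oob$prob[keep, , drop = FALSE]
  Vk <- V[keep, , drop = FALSE]
  terms <- intersect(term_universe, colnames(prob))
  res <- lapply(terms, function(tm) term_auprc(prob[, tm], Vk[, tm]))
  names(res) <- terms
  filled <- zero_fill(term_universe, res)
  detail <- data.frame(
    term_id = term_universe,
    n_pos = vapply(term_universe, function(tm)
      if (tm %in% terms) res[[tm]]$n_pos else 0L, integer(1)),
    supported = vapply(term_universe, function(tm)
      if (tm %in% terms) res[[tm]]$supported else FALSE, logical(1)),
    auprc = unname(filled),
    row.names = NULL
  )
  list(auprc = filled, detail = detail)
}

#' Write per-term AUPRC results as TSV
#'
#' Columns: `term_id`, `n_pos`, `supported`, `auprc`.
#'
#' @param detail The `detail` data.frame from [score_terms()].
#' @param path Output path.
#' @export
write_term_results <- function(detail, path) {
  utils::write.table(detail, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(detail)
}
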