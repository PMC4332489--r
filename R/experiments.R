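# Experiment drivers: genome-count sweeps, annotation-fraction sweeps,
# Open-World-Assumption controls and the strain-redundancy control.
#
# Two pinned behaviours, matching the experimental designs they model:
#  * genome sweeps keep group annotations FIXED at their full-data values
#    and only restrict profile columns, so differences are attributable to
#    the genomes alone;
#  * annotation sweeps re-derive group annotations from the thinned
#    annotation table (nested subsampling, so sweeps are monotone in data
#    content).
# The scored term universe is always the set of terms passing the support
# filter on the FULL data, so mean AUPRCs are comparable across conditions.

#' Experiment configuration
#'
#' @param k_grid Genome-subset sizes to sweep (default: quarter, half and
#'   all of the available genomes).
#' @param fraction_grid Annotation fractions for the annotation sweep.
#' @param strategies Genome-selection strategies among `"random"`,
#'   `"maxdiv"`.
#' @param replicates Replicates for random selections; default 10.
#' @param n_trees,min_leaf,w0 Forest parameters (`mtry` is
#'   `ceiling(sqrt(k))` per condition). `n_trees` defaults to 500; sweep
#'   drivers are usually run with 100 for tractability.
#' @param support_fraction Minimum term support as a fraction of the number
#'   of groups; default 0.05.
#' @param min_support Absolute support threshold overriding
#'   `support_fraction` when non-`NULL` (e.g. 50).
#' @param half_fraction Group-annotation majority threshold; default 0.5.
#' @param owa_remove_fraction Fraction of annotations removed in the OWA
#'   "remove" control; default 0.6.
#' @param owa_min_terms Distinct-term threshold of the OWA "well-annotated"
#'   control; default 5.
#' @param seed Master seed; every selection, subsample and forest seed is
#'   derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(k_grid = NULL,
                              fraction_grid = c(0.2, 0.4, 0.6, 0.8, 1.0),
                              strategies = c("random", "maxdiv"),
                              replicates = 10,
                              n_trees = 500, min_leaf = 5, w0 = 0.75,
                              support_fraction = 0.05, min_support = NULL,
                              half_fraction = 0.5,
                              owa_remove_fraction = 0.6, owa_min_terms = 5,
                              seed = 1) {
  stopifnot(all(fraction_grid >= 0 & fraction_grid <= 1),
            all(strategies %in% c("random", "maxdiv")),
            replicates >= 1, n_trees >= 1)
  structure(list(k_grid = k_grid, fraction_grid = fraction_grid,
                 strategies = strategies, replicates = replicates,
                 n_trees = n_trees, min_leaf = min_leaf, w0 = w0,
                 support_fraction = support_fraction,
                 min_support = min_support, half_fraction = half_fraction,
                 owa_remove_fraction = owa_remove_fraction,
                 owa_min_terms = owa_min_terms, seed = seed),
            class = "experiment_config")
}

#' Precompute the fixed full-data state of an experiment
#'
#' Builds the profile matrix, full-data group annotations, the fixed term
#' universe (terms passing the support filter on the full data, roots
#' excluded), hierarchy weights and full-data class vectors.
#'
#' @param world A `synthetic_world` (or any list with `groups`,
#'   `annotations`, `dag`, `genome_ids`, `distances`).
#' @param config An `experiment_config`.
#' @return List of class `experiment_prep`.
#' @export
prepare_experiment <- function(world, config = experiment_config()) {
  profiles <- build_profiles(world$groups, world$genome_ids)
  ga_full <- annotate_groups(world$groups, world$annotations, world$dag,
                             half_fraction = config$half_fraction)
  min_support <- if (!is.null(config$min_support)) config$min_support
                 else max(1L, round(config$support_fraction * nrow(profiles)))
  universe <- setdiff(filter_terms(ga_full, min_support), world$dag$roots)
  if (length(universe) == 0L)
    warning("no term passes the support filter on the full data")
  w <- hierarchy_weights(world$dag, config$w0)
  V_full <- build_class_vectors(ga_full, rownames(profiles), universe)
  ann_counts <- genome_annotation_counts(world$groups, world$annotations,
                                         world$genome_ids)
  structure(list(world = world, config = config, profiles = profiles,
                 ga_full = ga_full, min_support = min_support,
                 universe = universe, weights = w, V_full = V_full,
                 ann_counts = ann_counts),
            class = "experiment_prep")
}

# deterministic per-condition seed shared across sweep drivers, so equal
# (strategy, k, replicate) conditions coincide wherever they recur
condition_seed <- function(seed, strategy, k, replicate, stage) {
  s_code <- match(strategy, c("random", "maxdiv", "clade", "list", "all"))
  sub_seed(seed, s_code * 1e7 + k * 1e3 + replicate * 10 + stage)
}

select_for_condition <- function(prep, strategy, k, replicate) {
  cfg <- prep$config
  gids <- prep$world$genome_ids
  if (k > length(gids)) return(NULL)
  switch(strategy,
    random = select_random(gids, k,
                           seed = condition_seed(cfg$seed, "random", k, replicate, 1),
                           replicate = replicate),
    maxdiv = select_max_diversity(prep$world$distances[gids, gids],
                                  prep$ann_counts, k),
    stop("unknown strategy: ", strategy))
}

#' Run one experimental condition end to end
#'
#' Restricts the profile matrix to the selected genome columns, takes the
#' supplied class vectors (full-data ones for genome sweeps, re-derived
#' ones for annotation sweeps/OWA controls), fits a bagged HMC forest,
#' computes out-of-bag per-term AUPRC and zero-fills over the fixed term
#' universe. When no term of the universe has a positive label the
#' condition yields all zeros with a warning.
#'
#' @param prep An `experiment_prep`.
#' @param genomes Character vector of genome columns to use.
#' @param V Class-vector matrix (rows = all groups, columns = universe).
#' @param forest_seed Seed for bagging and tree growth.
#' @return List: `auprc` (named zero-filled vector), `mean`, `detail`.
#' @export
run_condition <- function(prep, genomes, V = prep$V_full, forest_seed = 1) {
  cfg <- prep$config
  X <- prep$profiles[, genomes, drop = FALSE]
  if (length(prep$universe) == 0L || sum(V) == 0) {
    warning("no supported term in this condition; emitting zeros")
    filled <- stats::setNames(numeric(length(prep$universe)), prep$universe)
    return(list(auprc = filled, mean = if (length(filled)) 0 else NA_real_,
                detail = NULL))
  }
  forest <- fit_hmc_forest(X, V, prep$weights$weight[colnames(V)],
                           n_trees = cfg$n_trees,
                           mtry = ceiling(sqrt(ncol(X))),
                           min_leaf = cfg$min_leaf, seed = forest_seed)
  oob <- oob_predict(forest, X)
  sc <- score_terms(oob, V, prep$universe)
  list(auprc = sc$auprc, mean = mean_auprc(sc$auprc), detail = sc$detail)
}

results_row <- function(experiment, strategy, k, fraction, owa_mode,
                        replicate, auprc) {
  data.frame(experiment = experiment, strategy = strategy, k = k,
             fraction = fraction, owa_mode = owa_mode, replicate = replicate,
             term_id = names(auprc), auprc = unname(auprc),
             stringsAsFactors = FALSE, row.names = NULL)
}

summarize_results <- function(per_term) {
  agg <- stats::aggregate(auprc ~ experiment + strategy + k + fraction +
                            owa_mode + replicate, data = per_term, FUN = mean)
  names(agg)[names(agg) == "auprc"] <- "mean_auprc"
  cond <- stats::aggregate(mean_auprc ~ experiment + strategy + k + fraction +
                             owa_mode, data = agg, FUN = mean)
  list(replicate_means = agg[order(agg$strategy, agg$k, agg$fraction,
                                   agg$replicate), ],
       condition_means = cond[order(cond$strategy, cond$k, cond$fraction), ])
}

as_results_table <- function(per_term) {
  out <- summarize_results(per_term)
  structure(list(per_term = per_term,
                 replicate_means = out$replicate_means,
                 condition_means = out$condition_means),
            class = "results_table")
}

#' Genome-count sweep
#'
#' For every k of the grid, runs the random strategy over `replicates`
#' seeds and the maximum-diversity strategy once, keeping group
#' annotations fixed at their full-data values. Values of k larger than
#' the number of genomes are skipped with a warning.
#'
#' @param world A `synthetic_world`.
#' @param config An `experiment_config`.
#' @return A `results_table`: `per_term` (long per-term AUPRC rows),
#'   `replicate_means`, `condition_means` (replicate-averaged).
#' @export
run_genome_sweep <- function(world, config = experiment_config()) {
  prep <- prepare_experiment(world, config)
  run_genome_sweep_prep(prep)
}

run_genome_sweep_prep <- function(prep, V = prep$V_full, owa_mode = "none",
                                  experiment = "genome_sweep") {
  cfg <- prep$config
  k_grid <- resolve_k_grid(cfg, prep$world$genome_ids)
  rows <- list()
  for (k in k_grid) {
    for (strategy in cfg$strategies) {
      reps <- if (strategy == "random") seq_len(cfg$replicates) else 1L
      for (r in reps) {
        sel <- select_for_condition(prep, strategy, k, r)
        res <- run_condition(prep, sel$genomes, V,
                             forest_seed = condition_seed(cfg$seed, strategy,
                                                          k, r, 2))
        rows[[length(rows) + 1L]] <-
          results_row(experiment, strategy, k, 1, owa_mode, r, res$auprc)
      }
    }
  }
  as_results_table(do.call(rbind, rows))
}

resolve_k_grid <- function(cfg, genome_ids) {
  n <- length(genome_ids)
  k_grid <- if (is.null(cfg$k_grid))
    unique(pmax(1L, round(n * c(0.25, 0.5, 1)))) else cfg$k_grid
  drop <- k_grid > n
  if (any(drop)) {
    warning("k value(s) exceeding the ", n, " available genomes skipped: ",
            paste(k_grid[drop], collapse = ", "))
    k_grid <- k_grid[!drop]
  }
  sort(unique(as.integer(k_grid)))
}

#' Annotation-fraction sweep
#'
#' For every fraction of the grid, subsamples the annotation table (nested
#' per replicate seed, so larger fractions contain smaller ones),
#' re-derives group annotations and class vectors from the thinned table,
#' and runs the genome strategies of the config at every k. The term
#' universe stays fixed at the full-data one; terms that lose all support
#' score zero.
#'
#' @inheritParams run_genome_sweep
#' @return A `results_table`.
#' @export
run_annotation_sweep <- function(world, config = experiment_config()) {
  prep <- prepare_experiment(world, config)
  cfg <- prep$config
  k_grid <- resolve_k_grid(cfg, world$genome_ids)
  rows <- list()
  for (r in seq_len(cfg$replicates)) {
    sub_base_seed <- sub_seed(cfg$seed, 7000 + r)
    for (fraction in sort(cfg$fraction_grid)) {
      ann <- subsample_annotations(world$annotations, fraction, sub_base_seed)
      ga <- annotate_groups(world$groups, ann, world$dag,
                            half_fraction = cfg$half_fraction)
      V <- build_class_vectors(ga, rownames(prep$profiles), prep$universe)
      for (k in k_grid) {
        for (strategy in cfg$strategies) {
          if (strategy != "random" && r > 1L) next
          sel <- select_for_condition(prep, strategy, k, r)
          res <- suppressWarnings(
            run_condition(prep, sel$genomes, V,
                          forest_seed = condition_seed(cfg$seed, strategy,
                                                       k, r, 2)))
          rows[[length(rows) + 1L]] <-
            results_row("annotation_sweep", strategy, k, fraction, "none",
                        r, res$auprc)
        }
      }
    }
  }
  as_results_table(do.call(rbind, rows))
}

#' Open-World-Assumption controls
#'
#' Two control designs around the incompleteness of annotation databases:
#' `"well_annotated"` keeps only genes with at least `owa_min_terms`
#' distinct raw annotations (a less OWA-biased subset), `"remove"` drops
#' `owa_remove_fraction` of all annotation rows at random (a more
#' OWA-biased subset). Both re-derive group annotations from the filtered
#' table and then run the genome sweep; the unfiltered sweep (`"none"`) is
#' included for comparison.
#'
#' @inheritParams run_genome_sweep
#' @param modes Subset of `c("none", "well_annotated", "remove")`.
#' @return A `results_table` with `owa_mode` distinguishing the arms.
#' @export
run_owa_controls <- function(world, config = experiment_config(),
                             modes = c("none", "remove", "well_annotated")) {
  prep <- prepare_experiment(world, config)
  cfg <- prep$config
  rows <- list()
  for (mode in modes) {
    ann <- switch(mode,
      none = world$annotations,
      remove = subsample_annotations(world$annotations,
                                     1 - cfg$owa_remove_fraction,
                                     sub_seed(cfg$seed, 8001)),
      well_annotated = well_annotated_genes(world$annotations,
                                            cfg$owa_min_terms),
      stop("unknown OWA mode: ", mode))
    if (mode != "none" && nrow(ann) == 0L) {
      warning("OWA mode '", mode, "' empties the annotation table; ",
              "condition aborted")
      next
    }
    V <- if (mode == "none") prep$V_full else {
      ga <- annotate_groups(world$groups, ann, world$dag,
                            half_fraction = cfg$half_fraction)
      build_class_vectors(ga, rownames(prep$profiles), prep$universe)
    }
    tab <- suppressWarnings(
      run_genome_sweep_prep(prep, V = V, owa_mode = mode,
                            experiment = "owa_controls"))
    rows[[length(rows) + 1L]] <- tab$per_term
  }
  if (length(rows) == 0L) stop("all OWA modes aborted")
  as_results_table(do.call(rbind, rows))
}

#' Strain-redundancy control
#'
#' Requires a world with a strain block (see [add_strain_block()]). For
#' each addition size r in `1:4` times the strain-set size, compares two
#' arms over `replicates` random draws: the strain set plus r random
#' non-strain organisms, versus the r random organisms alone. Group
#' annotations stay fixed at their full-data values, so the arms differ
#' only in the genome columns.
#'
#' @inheritParams run_genome_sweep
#' @param sizes Multiples of the strain-set size to add; default `1:4`.
#' @return A `results_table`; `strategy` holds the arm
#'   (`"strains+random"` / `"random"`), `k` the number of random organisms
#'   added.
#' @export
run_strain_redundancy <- function(world, config = experiment_config(),
                                  sizes = 1:4) {
  if (is.null(world$strains))
    stop("world has no strain block; call add_strain_block() first")
  prep <- prepare_experiment(world, config)
  cfg <- prep$config
  strain_set <- c(world$strains$base, world$strains$ids)
  pool <- setdiff(world$genome_ids, strain_set)
  n_set <- length(strain_set)
  rows <- list()
  for (s in sizes) {
    r_add <- s * n_set
    if (r_add > length(pool)) {
      warning("addition size ", r_add, " exceeds the ", length(pool),
              " available non-strain genomes; skipped")
      next
    }
    for (rep in seq_len(cfg$replicates)) {
      random_sel <- select_random(pool, r_add,
                                  seed = condition_seed(cfg$seed, "random",
                                                        r_add, rep, 3),
                                  replicate = rep)
      arms <- list("strains+random" = c(strain_set, random_sel$genomes),
                   "random" = random_sel$genomes)
      for (arm in names(arms)) {
        res <- run_condition(prep, arms[[arm]], prep$V_full,
                             forest_seed = condition_seed(cfg$seed, "random",
                                                          r_add, rep, 4))
        rows[[length(rows) + 1L]] <-
          results_row("strain_redundancy", arm, r_add, 1, "none", rep,
                      res$auprc)
      }
    }
  }
  as_results_table(do.call(rbind, rows))
}

#' Write a results table as TSV (+ JSON sidecar of condition means)
#'
#' @param tab A `results_table`.
#' @param path Output TSV path for the per-term rows; condition means go to
#'   `paste0(path, ".summary.json")`.
#' @export
write_results_table <- function(tab, path) {
  stopifnot(inherits(tab, "results_table"))
  utils::write.table(tab$per_term, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(tab$condition_means, paste0(path, ".summary.json"),
                       dataframe = "rows", digits = NA)
  invisible(path)
}
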