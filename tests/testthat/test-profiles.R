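make_ann_file <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

test_that("read_annotations filters by evidence code and deduplicates", {
  f <- make_ann_file(c("g1\tT:5\tIDA", "g2\tT:5\tIEA", "g3\tT:6\tND"))
  kept <- read_annotations(f, "IDA")
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "n_dropped"), 2L)

  all_kept <- read_annotations(f, c("IDA", "IEA", "ND"))
  expect_equal(nrow(all_kept), 3L)

  dup <- make_ann_file(c("g1\tT:5\tIDA", "g1\tT:5\tIDA"))
  expect_equal(nrow(read_annotations(dup, "IDA")), 1L)

  malformed <- make_ann_file(c("g1\tT:5\tIDA", "broken-row"))
  expect_warning(out <- read_annotations(malformed, "IDA"), "malformed")
  expect_equal(nrow(out), 1L)
})

test_that("read_annotations picks columns 2/5/7 from 17-column GAF", {
  gaf_row <- function(gene, term, ev) paste(
    c("DB", gene, "SYM", "", term, "REF", ev, "", "P", "", "", "protein",
      "taxon:1", "20130101", "DB", "", ""), collapse = "\t")
  f <- make_ann_file(c("!gaf-version: 2.0",
                       gaf_row("gA", "T:1", "IDA"),
                       gaf_row("gB", "T:2", "IEA")))
  out <- read_annotations(f)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$term_id, "T:1")
})

test_that("build_profiles marks presence per genome and commutes with projection", {
  groups <- data.frame(
    group_id = c("A", "A", "B", "B", "B"),
    species_id = c("s1", "s3", "s2", "s3", "s4"),
    gene_id = paste0("g", 1:5))
  m <- build_profiles(groups, c("s1", "s2", "s3"))
  expect_equal(unname(m["A", ]), c(1L, 0L, 1L))
  expect_equal(unname(m["B", ]), c(0L, 1L, 1L))
  expect_equal(unname(build_profiles(groups, "s2")["A", ]), 0L)
  expect_error(build_profiles(groups, character(0)), "non-empty")

  # brute-force per-cell check on a random membership table
  set.seed(4)
  rg <- data.frame(group_id = sample(paste0("G", 1:6), 40, replace = TRUE),
                   species_id = sample(paste0("s", 1:5), 40, replace = TRUE))
  rg$gene_id <- paste0(rg$group_id, "_", rg$species_id, "_", seq_len(40))
  genomes <- paste0("s", 1:5)
  full <- build_profiles(rg, genomes)
  for (g in rownames(full))
    for (s in genomes)
      expect_equal(full[g, s],
                   as.integer(any(rg$group_id == g & rg$species_id == s)))

  # column restriction equals building directly on the restricted list
  sub <- c("s2", "s4")
  expect_equal(full[, sub], build_profiles(rg, sub))
})

test_that("annotate_groups applies propagation then the at-least-half rule", {
  dag <- chain_dag()
  grp2 <- data.frame(group_id = "G", species_id = c("s1", "s2"),
                     gene_id = c("g1", "g2"))
  ann1 <- data.frame(gene_id = "g1", term_id = "T:1", evidence_code = "IDA")
  ga <- annotate_groups(grp2, ann1, dag)
  expect_equal(ga$terms[["G"]], "T:1")  # 1/2 meets "at least half"

  grp3 <- data.frame(group_id = "G", species_id = paste0("s", 1:3),
                     gene_id = paste0("g", 1:3))
  expect_equal(annotate_groups(grp3, ann1, dag)$terms[["G"]], character(0))

  # propagation makes both genes carry the shared ancestors T:1 and T:2;
  # T:3 is held by 1 of 2 members, which still meets "at least half"
  ann2 <- data.frame(gene_id = c("g1", "g2"), term_id = c("T:3", "T:2"),
                     evidence_code = "IDA")
  ga2 <- annotate_groups(grp2, ann2, dag)
  expect_equal(ga2$terms[["G"]], c("T:1", "T:2", "T:3"))
  # ancestors shared by both members survive a stricter threshold; T:3 not
  ga2b <- annotate_groups(grp2, ann2, dag, half_fraction = 0.75)
  expect_equal(ga2b$terms[["G"]], c("T:1", "T:2"))
  expect_equal(unname(ga2$support[c("T:1", "T:2", "T:3")]), c(1L, 1L, 1L))

  # unknown terms are dropped with a warning
  ann3 <- rbind(ann2, data.frame(gene_id = "g1", term_id = "T:99",
                                 evidence_code = "IDA"))
  expect_warning(ga3 <- annotate_groups(grp2, ann3, dag), "absent")
  expect_equal(ga3$terms[["G"]], c("T:1", "T:2", "T:3"))

  # a single-member group inherits exactly that member's propagated set
  grp1 <- data.frame(group_id = "H", species_id = "s1", gene_id = "g9")
  ann4 <- data.frame(gene_id = "g9", term_id = "T:3", evidence_code = "IDA")
  expect_equal(annotate_groups(grp1, ann4, dag)$terms[["H"]],
               propagate_terms("T:3", dag))
})

test_that("filter_terms applies an inclusive threshold and nests", {
  ga <- structure(list(terms = list(), support = c("T:1" = 50L, "T:2" = 49L)),
                  class = "group_annotations")
  expect_equal(filter_terms(ga, 50), "T:1")
  expect_equal(filter_terms(ga, 1), c("T:1", "T:2"))
  # stricter thresholds select a subset of looser ones
  ga2 <- annotate_groups(tiny_world()$groups, tiny_world()$annotations,
                         tiny_world()$dag)
  expect_true(all(filter_terms(ga2, 10) %in% filter_terms(ga2, 5)))
})

test_that("subsample_annotations is nested, deterministic and boundary-exact", {
  ann <- data.frame(gene_id = paste0("g", 1:10), term_id = "T:1",
                    evidence_code = "IDA")
  expect_identical(subsample_annotations(ann, 1, 3), ann)
  expect_equal(nrow(subsample_annotations(ann, 0, 3)), 0L)
  expect_equal(nrow(subsample_annotations(ann, 0.4, 3)), 4L)
  expect_error(subsample_annotations(ann, 1.2, 3), "fraction")

  expect_identical(subsample_annotations(ann, 0.5, 11),
                   subsample_annotations(ann, 0.5, 11))

  # nesting: rows kept at f are kept at every f' > f under the same seed
  for (seed in c(1, 2)) {
    prev <- character(0)
    for (f in c(0.2, 0.5, 0.8, 1)) {
      rows <- subsample_annotations(ann, f, seed)$gene_id
      expect_true(all(prev %in% rows))
      prev <- rows
    }
  }
})

test_that("well_annotated_genes counts distinct pre-propagation terms", {
  ann <- rbind(
    data.frame(gene_id = "rich", term_id = paste0("T:", 1:5),
               evidence_code = "IDA"),
    data.frame(gene_id = "mid", term_id = paste0("T:", 1:4),
               evidence_code = "IDA"),
    data.frame(gene_id = "dup", term_id = rep("T:1", 5),
               evidence_code = "IDA"))
  kept <- well_annotated_genes(ann, 5)
  expect_setequal(unique(kept$gene_id), "rich")
})
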