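# Proteome filter cascade: exact set algebra, classification rules,
# soluble overlap, and property tests against the brute-force oracle.

tbl <- function(ids, sample_id = "s", role = "experiment",
                intensity = rep(1, length(ids))) {
  replicate_table(sample_id, role, ids, intensity)
}

test_that("control exclusion removes proteins irrespective of intensity", {
  exps <- list(tbl(c("A", "B", "X")), tbl(c("A", "X"), "s2"))
  ctrl <- list(tbl("X", "c1", "control", intensity = 0.001))
  out <- subtract_controls(exps, ctrl)
  expect_identical(out[[1]]$protein_id, c("A", "B"))
  expect_identical(out[[2]]$protein_id, "A")
  # intensities of the survivors untouched
  expect_identical(out[[1]]$intensity, c(1, 1))
  # empty controls leave experiments unchanged
  out2 <- subtract_controls(exps, list(tbl(character(0), "c0", "control")))
  expect_identical(out2[[1]]$protein_id, exps[[1]]$protein_id)
  expect_error(subtract_controls(list(), ctrl), "experiment")
  expect_error(replicate_table("s", "experiment", c("A", "a")), "duplicate")
})

test_that("replicate consensus applies the at-least-k rule", {
  tabs <- list(tbl(c("A", "B")), tbl(c("A", "C")), tbl(c("A", "B", "D")))
  expect_identical(consolidate_replicates(tabs, 2), c("a", "b"))
  expect_identical(consolidate_replicates(tabs, 3), "a")
  expect_identical(consolidate_replicates(tabs, 1), c("a", "b", "c", "d"))
})

test_that("GO partition is an exact intersection/difference", {
  db <- annotation_db(go_mito = c("A", "B"), go_er = "C")
  p <- partition_by_go(c("A", "C", "D"), db, "mito")
  expect_identical(p$annotated, "a")
  expect_identical(p$non_annotated, c("c", "d"))
  p0 <- partition_by_go(character(0), db, "mito")
  expect_length(p0$annotated, 0)
  expect_length(p0$non_annotated, 0)
  pe <- partition_by_go(c("A", "B"), db, "er")
  expect_length(pe$annotated, 0)
})

test_that("interactor classification voids mRNA-binder actin hits", {
  db <- annotation_db(actin_interactors = c("A", "B", "M"),
                      tubulin_interactors = c("B", "T", "M"),
                      mrna_binder_exclusions = "M")
  cls <- classify_interactors(c("A", "B", "T", "M", "N"), db)
  expect_identical(unname(cls[c("a", "b", "t", "n")]),
                   c("actin_only", "both", "tubulin_only", "neither"))
  # actin membership voided by the exclusion; tubulin membership remains
  expect_identical(unname(cls["m"]), "tubulin_only")
  db2 <- annotation_db(actin_interactors = c("A", "M"),
                       mrna_binder_exclusions = "M")
  expect_identical(unname(classify_interactors("M", db2)["m"]), "neither")
})

test_that("soluble overlap respects membrane removal and tie-break", {
  ab <- c(p1 = 10, p2 = 9, p3 = 9, p4 = 8, m1 = 20)
  db <- annotation_db(go_membrane = "m1", abundance = ab)
  # top 2 by abundance among solubles: p1 (10) and the tie p2/p3 (9, 9)
  ov <- soluble_overlap(c("p2", "p3", "p4"), db, top_n = 2)
  expect_identical(ov$top_overlap, c("p2", "p3"))
  expect_identical(ov$all_overlap, c("p2", "p3", "p4"))
  expect_equal(unname(ov$counts$top["percentage"]), round(100 * 2 / 3))
  # membrane protein never counts as soluble
  ov2 <- soluble_overlap("m1", db, top_n = 2)
  expect_length(ov2$top_overlap, 0)
  expect_warning(soluble_overlap("p1", db, top_n = 10), "top_n")
})

test_that("cascade reproduces planted truth and the reported percentages", {
  st <- c(actin_only = 13, tubulin_only = 1, both = 5)
  g <- gen_proteomics_tables(n_true = 129, frac_go_mito = 0.2,
                             interactor_structure = st, seed = 42)
  rep_ <- run_filter_cascade(g$experiments, g$controls, g$db)
  tp <- g$truth$params
  expect_identical(rep_$consensus_set, tolower(tp$true_set))
  expect_identical(rep_$mito_annotated, tolower(tp$go_mito))
  expect_identical(rep_$er_annotated, tolower(tp$go_er))
  cnt <- attr(rep_$classification, "counts")
  expect_equal(unname(cnt[c("actin_only", "tubulin_only", "both")]),
               unname(st))
  expect_identical(names(which(rep_$classification == "actin_only")),
                   tolower(tp$actin_only))
  # percentages recompute from counts
  oc <- rep_$overlap_counts
  expect_equal(unname(oc$top["percentage"]),
               round(100 * oc$top["count"] / length(rep_$consensus_set),
                     0)[[1]])
  # FilterReport invariants
  expect_identical(sort(c(rep_$mito_annotated, rep_$non_annotated)),
                   rep_$consensus_set)
  expect_length(intersect(rep_$mito_annotated, rep_$non_annotated), 0)
  expect_true(all(names(rep_$classification) %in% rep_$consensus_set))
})

test_that("cascade equals the brute-force oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    p <- random_proteome_params()
    g <- do.call(gen_proteomics_tables, c(p, list(seed = i)))
    rep_ <- run_filter_cascade(g$experiments, g$controls, g$db)
    expect_cascade_matches_oracle(
      rep_, oracle_cascade(g$experiments, g$controls, g$db))
  }
})

test_that("enlarging controls or raising min_replicates shrinks consensus", {
  g <- gen_proteomics_tables(n_true = 40, seed = 7,
                             interactor_structure = c(actin_only = 4,
                                                      tubulin_only = 1,
                                                      both = 2))
  base <- run_filter_cascade(g$experiments, g$controls, g$db)
  # add a consensus protein to a control: it must disappear
  extra <- base$consensus_set[1]
  ctrl2 <- c(g$controls,
             list(replicate_table("c3", "control", extra, 5)))
  shrunk <- run_filter_cascade(g$experiments, ctrl2, g$db)
  expect_identical(shrunk$consensus_set, setdiff(base$consensus_set, extra))
  stricter <- run_filter_cascade(g$experiments, g$controls, g$db,
                                 min_replicates = 3)
  expect_true(all(stricter$consensus_set %in% base$consensus_set))
})
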