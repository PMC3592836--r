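test_that("Fisher upper-tail p on worked examples", {
  # a term annotating everything cannot be over-represented
  ann_all <- data.frame(
    transcript_id = paste0("t", 1:30), term_id = "GO:X"
  )
  enr <- fisher_enrichment(paste0("t", 1:5), paste0("t", 1:30), ann_all)
  expect_equal(enr$p_value, 1)
  expect_false(enr$enriched)

  # test 10 (8 annotated), reference-excluding-test 100 (10 annotated):
  # upper tail of Hypergeometric(N = 110, K = 18, n = 10) at >= 8
  p <- fisher_p_upper(8, 2, 10, 90)
  expect_equal(p, brute_hyper_tail(8, 2, 10, 90), tolerance = 1e-12)
  expect_equal(p,
    stats::fisher.test(
      matrix(c(8, 2, 10, 90), 2, byrow = TRUE),
      alternative = "greater"
    )$p.value,
    tolerance = 1e-9
  )

  # identical proportions give no over-representation signal
  expect_gte(fisher_p_upper(2, 8, 20, 80), 0.5)
  expect_error(
    fisher_enrichment(character(), paste0("t", 1:3), ann_all), "empty"
  )
  expect_error(
    fisher_enrichment("zzz", paste0("t", 1:3), ann_all), "subset"
  )
})

test_that("enrichment table margins are consistent and BH-controlled", {
  set.seed(121)
  universe <- sprintf("t%03d", 1:300)
  test_set <- universe[1:50]
  ann <- data.frame(
    transcript_id = sample(universe, 400, replace = TRUE),
    term_id = sample(sprintf("GO:%02d", 1:8), 400, replace = TRUE)
  )
  ann <- unique(ann)
  enr <- fisher_enrichment(test_set, universe, ann)
  expect_true(all(enr$test_in + enr$test_out == 50))
  expect_true(all(enr$ref_in + enr$ref_out == 250))
  expect_true(all(enr$fdr >= enr$p_value))
  expect_equal(enr$fdr, adjust_fdr(enr$p_value))
  for (i in seq_len(nrow(enr))) {
    expect_equal(
      enr$p_value[i],
      brute_hyper_tail(
        enr$test_in[i], enr$test_out[i], enr$ref_in[i], enr$ref_out[i]
      ),
      tolerance = 1e-10
    )
  }
})

test_that("a term covering the whole test set tops the ranking", {
  set.seed(122)
  universe <- sprintf("t%03d", 1:1010)
  test_set <- universe[1:10]
  ann <- rbind(
    data.frame(transcript_id = test_set, term_id = "GO:TOP"),
    data.frame(
      transcript_id = universe[11:20], term_id = "GO:TOP"
    ), # ~1% of reference
    data.frame(
      transcript_id = sample(universe, 300), term_id = "GO:BG"
    )
  )
  enr <- fisher_enrichment(test_set, universe, ann)
  expect_equal(enr$term_id[1], "GO:TOP")
  expect_true(enr$enriched[1])
})

test_that("null annotations are flagged at no more than the nominal rate", {
  cal <- calibrate_null_enrichment(
    n_reps = 30, n_transcripts = 500, n_terms = 40, test_size = 100,
    seed = 7
  )
  expect_lte(cal$flag_rate, 0.01 + 3 * cal$se)
})

test_that("planted enriched terms are all recovered", {
  sim <- tiny_sim(seed = 131, n_genes = 400)
  g <- validate_go_recovery(sim)
  expect_gte(g$test_size, 100)
  expect_equal(g$flagged_fraction, 1)
})

diamond_ontology <- function() {
  terms <- data.frame(
    term_id = c("root", "a", "b", "t"),
    name = c("root", "a", "b", "t"),
    namespace = "bp"
  )
  edges <- data.frame(
    term_id = c("a", "b", "t", "t"),
    parent_id = c("root", "root", "a", "b")
  )
  ontology_graph(terms, edges)
}

test_that("ontology levels follow the shortest is_a path, root = 1", {
  ont <- diamond_ontology()
  expect_equal(unname(ont$level[c("root", "a", "b", "t")]), c(1, 2, 2, 3))
  expect_error(
    ontology_graph(
      data.frame(term_id = c("x", "y")),
      data.frame(term_id = c("x", "y"), parent_id = c("y", "x"))
    ),
    "acyclic"
  )
})

test_that("level projection: identity at own level, diamond fan-out, idempotence", {
  ont <- diamond_ontology()
  m_root <- data.frame(transcript_id = "tr1", term_id = "root")
  expect_equal(project_to_level(m_root, ont, 1)$term_id, "root")
  m_a <- data.frame(transcript_id = "tr1", term_id = "a")
  expect_equal(project_to_level(m_a, ont, 2)$term_id, "a")
  # a term above the requested level maps to nothing
  expect_equal(nrow(project_to_level(m_root, ont, 2)), 0)

  m_t <- data.frame(transcript_id = "tr1", term_id = "t")
  proj <- project_to_level(m_t, ont, 2)
  expect_setequal(proj$term_id, c("a", "b"))
  proj2 <- project_to_level(proj, ont, 2)
  expect_setequal(proj2$term_id, c("a", "b"))
  expect_equal(nrow(proj2), nrow(proj))

  expect_warning(
    project_to_level(
      data.frame(transcript_id = "tr1", term_id = "GO:MISSING"), ont, 2
    ),
    "absent"
  )
})

test_that("true-path propagation annotates all ancestors", {
  ont <- diamond_ontology()
  m <- data.frame(transcript_id = "tr1", term_id = "t")
  prop <- propagate_annotations(m, ont)
  expect_setequal(prop$term_id, c("t", "a", "b", "root"))
})

test_that("OBO reading builds the same graph", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0001", "name: root", "namespace: bp", "",
    "[Term]", "id: GO:0002", "name: mid", "namespace: bp",
    "is_a: GO:0001 ! root", "",
    "[Term]", "id: GO:0003", "name: leaf", "namespace: bp",
    "is_a: GO:0002 ! mid", "",
    "[Term]", "id: GO:0004", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"
  ), obo)
  ont <- read_obo(obo)
  expect_setequal(ont$terms$term_id, c("GO:0001", "GO:0002", "GO:0003"))
  expect_equal(unname(ont$level[c("GO:0001", "GO:0002", "GO:0003")]), 1:3)
  expect_equal(ont$roots, "GO:0001")
})

test_that("bin crosstab counts members per bin with a totals row", {
  expect_equal(nrow(crosstab_bins(
    data.frame(term_id = character(), fdr = numeric()),
    data.frame(transcript_id = character(), bin = character()),
    data.frame(transcript_id = character(), term_id = character())
  )), 0)

  bins <- data.frame(
    transcript_id = c("x", "y", "z"),
    bin = bin_fold_change(c(-2.5, -1, 3))
  )
  ann <- data.frame(transcript_id = c("x", "y", "z"), term_id = "GO:1")
  ct <- crosstab_bins(data.frame(term_id = "GO:1", fdr = 0.001), bins, ann)
  expect_equal(ct$Up2[1], 1)
  expect_equal(ct$Up1[1], 1)
  expect_equal(ct$Down2[1], 1)
  expect_equal(ct$Down1[1], 0)
  expect_equal(ct$term_id[2], "Total")
  expect_equal(unlist(ct[2, c("Up1", "Up2", "Down1", "Down2")]),
    c(Up1 = 1, Up2 = 1, Down1 = 0, Down2 = 1)
  )
})

test_that("the published level-4 crosstab totals give the strong-change share", {
  tab <- study_table("enriched_bin_counts")
  expect_equal(sum(tab$Up1), 511)
  expect_equal(sum(tab$Up2), 735)
  expect_equal(sum(tab$Down1), 42)
  expect_equal(sum(tab$Down2), 148)
  tab$fdr <- as.numeric(tab$fdr)
  expect_equal(extreme_bin_share(tab), 61.5)
})
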