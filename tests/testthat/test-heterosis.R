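make_calls <- function(patterns) {
  # patterns: named list transcript_id -> c(sHTi, sHTa, sPP)
  do.call(rbind, lapply(names(patterns), function(id) {
    data.frame(
      transcript_id = id,
      comparison = c("H_vs_P1", "H_vs_P2", "P1_vs_P2"),
      significant = as.logical(patterns[[id]]),
      stringsAsFactors = FALSE
    )
  }))
}

test_that("subgroup partition follows the significance pattern", {
  calls <- make_calls(list(
    a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1), d = c(1, 0, 1),
    e = c(0, 1, 1), f = c(1, 1, 0), g = c(1, 1, 1), h = c(0, 0, 0)
  ))
  part <- partition_subgroups(calls)
  got <- setNames(as.character(part$subgroup), part$transcript_id)
  expect_equal(got[["a"]], "HTiU")
  expect_equal(got[["b"]], "HTaU")
  expect_equal(got[["c"]], "PPU")
  expect_equal(got[["d"]], "HP1")
  expect_equal(got[["e"]], "HP2")
  expect_equal(got[["f"]], "HPco")
  expect_equal(got[["g"]], "co")
  expect_false("h" %in% part$transcript_id)
  expect_error(partition_subgroups(calls[calls$comparison != "P1_vs_P2", ]),
    "three comparisons"
  )
})

test_that("partition identities hold on random patterns", {
  set.seed(61)
  ids <- sprintf("t%03d", 1:200)
  patterns <- lapply(ids, function(i) rbinom(3, 1, 0.4))
  names(patterns) <- ids
  calls <- make_calls(patterns)
  part <- partition_subgroups(calls)
  tab <- table(part$subgroup)
  n_hti <- sum(vapply(patterns, function(p) p[1] == 1, logical(1)))
  n_hta <- sum(vapply(patterns, function(p) p[2] == 1, logical(1)))
  n_pp <- sum(vapply(patterns, function(p) p[3] == 1, logical(1)))
  expect_equal(
    unname(tab["HTiU"] + tab["HP1"] + tab["HPco"] + tab["co"]), n_hti
  )
  expect_equal(
    unname(tab["HTaU"] + tab["HP2"] + tab["HPco"] + tab["co"]), n_hta
  )
  expect_equal(
    unname(tab["PPU"] + tab["HP1"] + tab["HP2"] + tab["co"]), n_pp
  )
  expect_equal(sum(tab), sum(vapply(patterns, sum, numeric(1)) > 0))
})

test_that("gene-action classification on worked examples", {
  tau <- log(1.5)
  expect_equal(
    as.character(classify_gene_action(10, 2, 3, tau)$category), "above_high"
  )
  expect_equal(
    as.character(classify_gene_action(2.5, 2, 3, tau)$category), "mid_parent"
  )
  expect_equal(
    as.character(classify_gene_action(2.9, 2, 3, tau)$category), "high_parent"
  )
  expect_equal(
    as.character(classify_gene_action(0.1, 2, 3, tau)$category), "below_low"
  )
  expect_equal(
    as.character(classify_gene_action(2.05, 2, 3, tau)$category), "low_parent"
  )
  expect_equal(
    classify_gene_action(10, 2, 3, tau)$mode, "overdominance"
  )
  expect_equal(
    classify_gene_action(2.5, 2, 3, tau)$mode, "additivity"
  )
  expect_error(classify_gene_action(1, 1, 1, tolerance_tau = 0), "tau")
  # zero expression is well-defined through the pseudo-count
  expect_equal(
    as.character(classify_gene_action(0, 0, 0, tau)$category), "mid_parent"
  )
})

test_that("classification is invariant to swapping the parent labels", {
  set.seed(71)
  for (r in 1:50) {
    h <- rexp(1, 1 / 20)
    p1 <- rexp(1, 1 / 20)
    p2 <- rexp(1, 1 / 20)
    expect_identical(
      as.character(classify_gene_action(h, p1, p2)$category),
      as.character(classify_gene_action(h, p2, p1)$category)
    )
  }
})

test_that("fold-change bins partition the line with boundaries toward zero", {
  expect_equal(as.character(bin_fold_change(-2.5)), "Up2")
  expect_equal(as.character(bin_fold_change(-1)), "Up1")
  expect_equal(as.character(bin_fold_change(3)), "Down2")
  expect_equal(as.character(bin_fold_change(1)), "Down1")
  expect_equal(as.character(bin_fold_change(0)), "None")
  expect_equal(as.character(bin_fold_change(-2)), "Up1")
  expect_equal(as.character(bin_fold_change(2)), "Down1")
  expect_error(bin_fold_change(Inf), "finite")
  set.seed(81)
  x <- c(rnorm(500, 0, 2), -2, 2, 0)
  b <- bin_fold_change(x)
  expect_false(anyNA(b))
  expect_true(all(as.character(b[x != 0 & abs(x) != 2]) != "None"))
})

test_that("gene-action summary reproduces the published table arithmetic", {
  tab <- study_table("gene_action_counts")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    cats <- rep(GENE_ACTION_MODES, times = unlist(tab[i, GENE_ACTION_MODES]))
    if (length(cats) == 0) {
      return(NULL)
    }
    data.frame(
      transcript_id = sprintf("%s_%04d", tab$subgroup[i], seq_along(cats)),
      subgroup = tab$subgroup[i], category = cats, stringsAsFactors = FALSE
    )
  })
  flat <- do.call(rbind, rows)
  s <- summarize_actions(
    flat[, c("transcript_id", "subgroup")],
    flat[, c("transcript_id", "category")]
  )
  expect_equal(s$grand_total, 10952)
  expect_equal(
    unname(s$percent[GENE_ACTION_MODES]),
    c(6.8, 10.3, 4.6, 9.5, 68.7)
  )
  expect_equal(unname(s$counts["HPco", "Total"]), 2024)
  expect_equal(
    unname(s$counts["HPco", "Total"] + s$counts["co", "Total"]), 2237
  )
  expect_equal(unname(s$counts["Total", "Total"]), 10952)
})

test_that("gene-action summary equals a brute-force recount and rejects PPU", {
  set.seed(91)
  n <- 50
  sub <- sample(c("HTiU", "HP1", "HPco", "co", "HTaU", "HP2"), n, replace = TRUE)
  cat <- sample(GENE_ACTION_MODES, n, replace = TRUE)
  ids <- sprintf("t%02d", 1:n)
  s <- summarize_actions(
    data.frame(transcript_id = ids, subgroup = sub),
    data.frame(transcript_id = ids, category = cat)
  )
  for (sg in unique(sub)) {
    for (cc in unique(cat)) {
      expect_equal(unname(s$counts[sg, cc]), sum(sub == sg & cat == cc))
    }
  }
  s_empty <- summarize_actions(
    data.frame(transcript_id = character(), subgroup = character()),
    data.frame(transcript_id = character(), category = character())
  )
  expect_equal(s_empty$grand_total, 0)
  expect_error(
    summarize_actions(
      data.frame(transcript_id = "x", subgroup = "PPU"),
      data.frame(transcript_id = "x", category = "mid_parent")
    ),
    "PPU"
  )
})
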