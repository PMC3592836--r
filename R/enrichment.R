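# One-tailed Fisher exact GO over-representation, ontology level
# projection, and the fold-change-bin crosstab of enriched terms.

#' Upper-tail hypergeometric p-value for a 2x2 enrichment table
#'
#' Probability of observing at least `test_in` annotated members in the
#' test set, under the hypergeometric null (one-tailed Fisher's exact
#' test for over-representation).  Vectorized.
#'
#' @param test_in,test_out annotated / unannotated counts in the test set.
#' @param ref_in,ref_out annotated / unannotated counts in the reference
#'   set *excluding* the test set.
#' @return p-value(s) in `[0, 1]`.
#' @export
fisher_p_upper <- function(test_in, test_out, ref_in, ref_out) {
  if (any(c(test_in, test_out, ref_in, ref_out) < 0)) {
    contract_error("table counts must be >= 0")
  }
  k_annot <- test_in + ref_in
  n_test <- test_in + test_out
  n_total <- n_test + ref_in + ref_out
  stats::phyper(test_in - 1, k_annot, n_total - k_annot, n_test,
    lower.tail = FALSE
  )
}

#' GO-term over-representation of a test set
#'
#' One-tailed Fisher's exact test per term: is the term over-represented
#' in the test set relative to the reference set?  The reference margin
#' excludes test members (a two-set contrast), FDR is Benjamini-Hochberg
#' across all tested terms, and a term is flagged enriched when its FDR is
#' below `filter_value`.  Only terms annotating at least one test member
#' are tested.
#'
#' @param test_set character vector of transcript ids (must be a subset
#'   of `reference_set`).
#' @param reference_set character vector of transcript ids (the universe,
#'   e.g. all identified transcripts).
#' @param annotation_map data frame `transcript_id`, `term_id`.
#' @param filter_value FDR filter (default 0.01).
#' @return data frame `term_id`, `test_in`, `test_out`, `ref_in`,
#'   `ref_out`, `p_value`, `fdr`, `enriched`, ordered by p-value.
#' @export
fisher_enrichment <- function(test_set, reference_set, annotation_map,
                              filter_value = 0.01) {
  test_set <- unique(test_set)
  reference_set <- unique(reference_set)
  if (length(test_set) == 0) contract_error("test set is empty")
  if (nrow(annotation_map) == 0) contract_error("annotation map is empty")
  if (!all(test_set %in% reference_set)) {
    contract_error("test set must be a subset of the reference set")
  }
  ref_excl <- setdiff(reference_set, test_set)
  ann <- annotation_map[annotation_map$transcript_id %in% reference_set, ]
  in_test <- ann$transcript_id %in% test_set
  t_in <- table(factor(ann$term_id[in_test]))
  terms <- names(t_in)
  if (length(terms) == 0) {
    return(data.frame(
      term_id = character(), test_in = integer(), test_out = integer(),
      ref_in = integer(), ref_out = integer(), p_value = numeric(),
      fdr = numeric(), enriched = logical(), stringsAsFactors = FALSE
    ))
  }
  r_in_tab <- table(factor(ann$term_id[!in_test], levels = terms))
  test_in <- as.integer(t_in[terms])
  ref_in <- as.integer(r_in_tab[terms])
  test_out <- length(test_set) - test_in
  ref_out <- length(ref_excl) - ref_in
  p <- fisher_p_upper(test_in, test_out, ref_in, ref_out)
  fdr <- adjust_fdr(p)
  out <- data.frame(
    term_id = terms, test_in = test_in, test_out = test_out,
    ref_in = ref_in, ref_out = ref_out,
    p_value = p, fdr = fdr, enriched = fdr < filter_value,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' Crosstab of enriched terms by fold-change bin
#'
#' For each enriched (level-projected) term, counts its member transcripts
#' in each of the four fold-change bins, with a totals row and the term's
#' FDR carried along.
#'
#' @param enriched_terms data frame `term_id`, `fdr` (e.g. the enriched
#'   rows of [fisher_enrichment()] after [project_to_level()]).
#' @param transcript_bins data frame `transcript_id`, `bin` (levels as in
#'   [bin_fold_change()]).
#' @param annotation_map data frame `transcript_id`, `term_id` at the
#'   projected level.
#' @return data frame `term_id`, `Up1`, `Up2`, `Down1`, `Down2`, `fdr`,
#'   with a final `Total` row.
#' @export
crosstab_bins <- function(enriched_terms, transcript_bins, annotation_map) {
  bins <- c("Up1", "Up2", "Down1", "Down2")
  empty <- data.frame(
    term_id = character(), Up1 = integer(), Up2 = integer(),
    Down1 = integer(), Down2 = integer(), fdr = numeric(),
    stringsAsFactors = FALSE
  )
  if (nrow(enriched_terms) == 0) {
    return(empty)
  }
  rows <- lapply(seq_len(nrow(enriched_terms)), function(i) {
    tid <- enriched_terms$term_id[i]
    members <- annotation_map$transcript_id[annotation_map$term_id == tid]
    b <- transcript_bins$bin[transcript_bins$transcript_id %in% members]
    cnt <- table(factor(as.character(b), levels = bins))
    data.frame(
      term_id = tid, Up1 = cnt[["Up1"]], Up2 = cnt[["Up2"]],
      Down1 = cnt[["Down1"]], Down2 = cnt[["Down2"]],
      fdr = enriched_terms$fdr[i], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  total <- data.frame(
    term_id = "Total", Up1 = sum(out$Up1), Up2 = sum(out$Up2),
    Down1 = sum(out$Down1), Down2 = sum(out$Down2), fdr = NA_real_,
    stringsAsFactors = FALSE
  )
  rbind(out, total)
}

#' Share of strongly changed transcripts in a bin crosstab
#'
#' The percentage of binned transcripts whose absolute ln fold change
#' exceeds 2 (`Up2` + `Down2` over all four bins), half-up at one decimal.
#'
#' @param crosstab output of [crosstab_bins()] (the `Total` row is used
#'   when present, otherwise column sums).
#' @return percentage.
#' @export
extreme_bin_share <- function(crosstab) {
  x <- crosstab[crosstab$term_id != "Total", , drop = FALSE]
  tot <- sum(x$Up1, x$Up2, x$Down1, x$Down2)
  if (tot == 0) {
    return(0)
  }
  round_half_up(100 * (sum(x$Up2) + sum(x$Down2)) / tot, 1)
}
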