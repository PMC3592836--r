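# Self-validation experiments on synthetic data: planted-mode recovery,
# null calibration of the differential test, and null calibration of the
# enrichment stage.  These are the package's own operating
# characteristics, computed fresh on every run.

#' Planted-mode recovery on a synthetic study
#'
#' Runs quantification, differential calling and gene-action
#' classification on a simulated study and scores them against the
#' planted truth.  Recovery is evaluated on the transcripts called
#' differential in *both* hybrid comparisons — a gene-action mode is a
#' statement about the hybrid relative to both parents, and this is the
#' set the enrichment stage consumes.  Detection power is the fraction of
#' planted non-null transcripts significant in at least one of the three
#' comparisons (every non-null transcript carries a planted difference in
#' each comparison by construction).
#'
#' @param sim output of [simulate_study()].
#' @param alpha,tolerance_tau,pseudo_fpkm pipeline thresholds.
#' @return list: `recovery_pct` (correct planted category among scored
#'   transcripts), `n_scored`, `power_pct`, `n_nonnull`, plus the
#'   `de_calls`, `actions` and `expression` tables for reuse.
#' @export
validate_mode_recovery <- function(sim, alpha = 0.05,
                                   tolerance_tau = log(1.5),
                                   pseudo_fpkm = 0.1) {
  expression <- expression_table(sim$counts, sim$models)
  de <- call_de(expression,
    alpha = alpha, pseudo_fpkm = pseudo_fpkm,
    nb_dispersion = sim$config$nb_dispersion
  )
  sig <- function(cmp) {
    x <- de[de$comparison == cmp, ]
    stats::setNames(x$significant, x$transcript_id)
  }
  s1 <- sig("H_vs_P1")
  s2 <- sig("H_vs_P2")
  sp <- sig("P1_vs_P2")
  ids <- expression$transcript_id
  truth <- sim$truth[match(ids, sim$truth$transcript_id), ]
  nonnull <- truth$planted_mode != "null"

  cls <- classify_gene_action(
    expression$fpkm_H, expression$fpkm_P1, expression$fpkm_P2,
    tolerance_tau = tolerance_tau, pseudo_fpkm = pseudo_fpkm
  )
  scored <- nonnull & s1[ids] & s2[ids]
  correct <- as.character(cls$category) == truth$planted_mode
  recovery_pct <- if (any(scored)) 100 * mean(correct[scored]) else NA_real_
  power_pct <- if (any(nonnull)) {
    100 * mean((s1[ids] | s2[ids] | sp[ids])[nonnull])
  } else {
    NA_real_
  }
  list(
    recovery_pct = recovery_pct,
    n_scored = sum(scored),
    power_pct = power_pct,
    n_nonnull = sum(nonnull),
    de_calls = de,
    actions = data.frame(
      transcript_id = ids, category = cls$category,
      scored = scored, stringsAsFactors = FALSE
    ),
    expression = expression
  )
}

#' Planted GO-term recovery on a synthetic study
#'
#' Feeds the differential hybrid set (significant against both parents)
#' into the enrichment stage and reports which planted enriched terms are
#' flagged.
#'
#' @param sim output of [simulate_study()] (with `enrichment_factor > 1`).
#' @param recovery optional output of [validate_mode_recovery()] to reuse.
#' @param alpha,filter_value thresholds.
#' @return list: `flagged_fraction` of planted terms, `n_planted`,
#'   `enrichment` table, `test_size`.
#' @export
validate_go_recovery <- function(sim, recovery = NULL, alpha = 0.05,
                                 filter_value = 0.01) {
  if (is.null(recovery)) recovery <- validate_mode_recovery(sim, alpha = alpha)
  de <- recovery$de_calls
  both <- intersect(
    de$transcript_id[de$comparison == "H_vs_P1" & de$significant],
    de$transcript_id[de$comparison == "H_vs_P2" & de$significant]
  )
  ex <- recovery$expression
  detected <- ex$transcript_id[
    ex$fpkm_H > 0 | ex$fpkm_P1 > 0 | ex$fpkm_P2 > 0
  ]
  test_set <- intersect(both, detected)
  enr <- fisher_enrichment(
    test_set, detected, sim$annotations,
    filter_value = filter_value
  )
  flagged <- enr$term_id[enr$enriched]
  list(
    flagged_fraction = if (length(sim$enriched_terms) > 0) {
      mean(sim$enriched_terms %in% flagged)
    } else {
      NA_real_
    },
    n_planted = length(sim$enriched_terms),
    enrichment = enr,
    test_size = length(test_set)
  )
}

#' Null calibration of the differential test
#'
#' Monte-Carlo replicates of an all-null three-sample study (`frac_null =
#' 1`): every transcript has identical means across samples, counts are
#' negative-binomial with the configured dispersion, and [call_de()] is
#' run per replicate.  Reports the pooled fraction of raw p-values at or
#' below `alpha` (the type-I error of the test) and the pooled fraction
#' of FDR-significant calls.
#'
#' @param n_transcripts transcripts per replicate.
#' @param n_reps Monte-Carlo replicates.
#' @param alpha nominal level.
#' @param nb_dispersion,library_size generator/test settings.
#' @param seed master seed.
#' @return list: `raw_rate`, `fdr_rate`, `n_tests`, and the binomial
#'   `se` of `raw_rate` under the nominal level.
#' @export
calibrate_null_de <- function(n_transcripts = 2000, n_reps = 200,
                              alpha = 0.05, nb_dispersion = 0.1,
                              library_size = 1e6, seed = 1L) {
  base <- simulation_config(
    n_genes = n_transcripts, isoforms_per_gene = 1,
    frac_null = 1, nb_dispersion = nb_dispersion,
    library_size = library_size, seed = seed
  )
  models <- generate_gene_models(base)
  n_raw <- 0
  n_fdr <- 0
  n_tests <- 0
  for (r in seq_len(n_reps)) {
    cfg <- base
    cfg$seed <- (base$seed + r * 7919L) %% 2147483647L
    planted <- plant_expression(models, cfg)
    counts <- sample_counts(planted$means, models, cfg)
    de <- call_de(expression_table(counts, models),
      alpha = alpha, nb_dispersion = nb_dispersion
    )
    n_raw <- n_raw + sum(de$p_value <= alpha)
    n_fdr <- n_fdr + sum(de$significant)
    n_tests <- n_tests + nrow(de)
  }
  list(
    raw_rate = n_raw / n_tests,
    fdr_rate = n_fdr / n_tests,
    n_tests = n_tests,
    se = sqrt(alpha * (1 - alpha) / n_tests)
  )
}

#' Null calibration of the enrichment stage
#'
#' With `enrichment_factor = 1` no GO term is enriched by construction;
#' replicated annotation draws measure how often a term is still flagged
#' at `fdr < filter_value`.
#'
#' @param n_reps Monte-Carlo replicates.
#' @param n_transcripts universe size per replicate.
#' @param n_terms GO terms per replicate.
#' @param test_size size of the (arbitrary, fixed) test set.
#' @param background_rate annotation probability.
#' @param filter_value enrichment FDR filter.
#' @param seed master seed.
#' @return list: `flag_rate` (pooled fraction of tested terms flagged),
#'   `n_terms_tested`, `se` under the nominal `filter_value`.
#' @export
calibrate_null_enrichment <- function(n_reps = 200, n_transcripts = 2000,
                                      n_terms = 50, test_size = 200,
                                      background_rate = 0.05,
                                      filter_value = 0.01, seed = 1L) {
  cfg <- simulation_config(
    n_genes = n_transcripts, isoforms_per_gene = 1,
    frac_null = 1, seed = seed
  )
  models <- generate_gene_models(cfg)
  truth <- plant_expression(models, cfg)$truth
  ids <- truth$transcript_id
  test_set <- ids[seq_len(test_size)]
  n_flag <- 0
  n_tested <- 0
  for (r in seq_len(n_reps)) {
    go <- plant_go_annotations(models, truth,
      n_terms = n_terms,
      enrichment_factor = 1,
      seed = (seed + r * 104729L) %% 2147483647L,
      background_rate = background_rate
    )
    enr <- fisher_enrichment(test_set, ids, go$annotations,
      filter_value = filter_value
    )
    n_flag <- n_flag + sum(enr$enriched)
    n_tested <- n_tested + nrow(enr)
  }
  list(
    flag_rate = n_flag / n_tested,
    n_terms_tested = n_tested,
    se = sqrt(filter_value * (1 - filter_value) / n_tested)
  )
}
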