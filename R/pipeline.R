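# End-to-end orchestration: configuration, staged execution, report
# tables, and the run manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default.
#' Exactly one of `simulate` (a [simulation_config()]) or `paths` (a list
#' with `models` GTF, `counts` TSV, optionally `annotations` TSV,
#' `ontology` OBO, `reads` BED) must be supplied.
#'
#' @param simulate optional [simulation_config()].
#' @param paths optional named list of input paths.
#' @param alpha FDR threshold for differential calls.
#' @param min_abs_ln_ratio minimum |ln fold change| for significance.
#' @param pseudo_fpkm pseudo-FPKM stabilizer.
#' @param tolerance_tau gene-action log tolerance.
#' @param filter_value enrichment FDR filter.
#' @param go_level ontology level for the enrichment crosstab.
#' @param nb_dispersion count overdispersion phi used by the test (for
#'   simulated input it defaults to the generator's value).
#' @param enrich_set which hybrid differential set feeds the enrichment
#'   test: `"HPco"` (differential against both parents but not between
#'   them, the study's choice) or `"HPco_co"` (all transcripts
#'   differential against both parents).
#' @param outdir optional output directory for TSV reports + manifest.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            alpha = 0.05, min_abs_ln_ratio = 0,
                            pseudo_fpkm = 0.1, tolerance_tau = log(1.5),
                            filter_value = 0.01, go_level = 4,
                            nb_dispersion = NULL,
                            enrich_set = c("HPco", "HPco_co"),
                            outdir = NULL) {
  if (is.null(simulate) == is.null(paths)) {
    config_error("supply exactly one of 'simulate' or 'paths'")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    config_error("'simulate' must come from simulation_config()")
  }
  if (!is.null(paths) && !all(c("models", "counts") %in% names(paths))) {
    config_error("'paths' needs at least 'models' and 'counts'")
  }
  stopifnot_scalar_number(alpha, "alpha", min = 0)
  stopifnot_scalar_number(min_abs_ln_ratio, "min_abs_ln_ratio", min = 0)
  stopifnot_scalar_number(pseudo_fpkm, "pseudo_fpkm")
  stopifnot_scalar_number(tolerance_tau, "tolerance_tau")
  stopifnot_scalar_number(filter_value, "filter_value", min = 0)
  stopifnot_scalar_number(go_level, "go_level", min = 1)
  if (alpha > 1 || filter_value > 1) {
    config_error("alpha and filter_value must lie in [0, 1]")
  }
  if (is.null(nb_dispersion)) {
    nb_dispersion <- if (!is.null(simulate)) simulate$nb_dispersion else 0
  }
  structure(
    list(
      simulate = simulate, paths = paths, alpha = alpha,
      min_abs_ln_ratio = min_abs_ln_ratio, pseudo_fpkm = pseudo_fpkm,
      tolerance_tau = tolerance_tau, filter_value = filter_value,
      go_level = as.integer(go_level), nb_dispersion = nb_dispersion,
      enrich_set = match.arg(enrich_set), outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Run the full hybrid-versus-parents pipeline
#'
#' Quantification (FPKM, abundance summary, optional coverage) ->
#' differential calls for the three comparisons -> subgroup partition ->
#' gene-action classification and summary -> fold-change binning ->
#' GO enrichment of the configured hybrid set.  Deterministic given the
#' simulation seed; writes TSV reports and a JSON manifest when `outdir`
#' is configured.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return list with `expression`, `abundance`, `coverage`, `de_calls`,
#'   `subgroups`, `actions`, `action_summary`, `fold_bins`, `enrichment`,
#'   `crosstab`, `sim` (when simulated) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config_error("'config' must come from pipeline_config()")
  }
  say <- function(...) if (!quiet) message(...)

  sim <- NULL
  ontology <- NULL
  reads <- NULL
  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic study")
    sim <- simulate_study(config$simulate)
    models <- sim$models
    counts <- sim$counts
    annotations <- sim$annotations
  } else {
    say("stage input: reading user data")
    models <- read_transcript_models(config$paths$models)
    counts <- read_tsv(config$paths$counts)
    annotations <- if (!is.null(config$paths$annotations)) {
      stats::setNames(
        read_tsv(config$paths$annotations)[, 1:2],
        c("transcript_id", "term_id")
      )
    }
    if (!is.null(config$paths$ontology)) {
      ontology <- read_obo(config$paths$ontology)
    }
    if (!is.null(config$paths$reads)) reads <- read_bed(config$paths$reads)
  }

  say("stage quantify: FPKM and abundance summary")
  expression <- expression_table(counts, models)
  coverage <- if (!is.null(reads)) gene_coverage(models, reads)
  abundance <- summarize_abundance(expression)

  say("stage diffexp: three pairwise comparisons")
  de_calls <- call_de(expression,
    alpha = config$alpha,
    min_abs_ln_ratio = config$min_abs_ln_ratio,
    pseudo_fpkm = config$pseudo_fpkm,
    nb_dispersion = config$nb_dispersion
  )
  say(sprintf(
    "  significant calls: %d of %d tests",
    sum(de_calls$significant), nrow(de_calls)
  ))

  say("stage heterosis: subgroup partition and gene action")
  subgroups <- partition_subgroups(de_calls)
  hybrid <- subgroups[subgroups$subgroup != "PPU", , drop = FALSE]
  idx <- match(hybrid$transcript_id, expression$transcript_id)
  cls <- classify_gene_action(
    expression$fpkm_H[idx], expression$fpkm_P1[idx], expression$fpkm_P2[idx],
    tolerance_tau = config$tolerance_tau, pseudo_fpkm = config$pseudo_fpkm
  )
  actions <- data.frame(
    transcript_id = hybrid$transcript_id,
    category = cls$category, mode = cls$mode,
    stringsAsFactors = FALSE
  )
  action_summary <- summarize_actions(hybrid, actions)

  # one ln(x/H) per transcript for binning: the mean of the two parental
  # ratios, i.e. ln(geometric-mean parent / hybrid)
  lr1 <- de_calls$ln_ratio[de_calls$comparison == "H_vs_P1"]
  lr2 <- de_calls$ln_ratio[de_calls$comparison == "H_vs_P2"]
  ids <- de_calls$transcript_id[de_calls$comparison == "H_vs_P1"]
  fold_bins <- data.frame(
    transcript_id = ids,
    ln_ratio = (lr1 + lr2) / 2,
    bin = bin_fold_change((lr1 + lr2) / 2),
    stringsAsFactors = FALSE
  )

  enrichment <- NULL
  crosstab <- NULL
  if (!is.null(annotations) && nrow(annotations) > 0) {
    say("stage enrichment: one-tailed Fisher per GO term")
    wanted <- if (config$enrich_set == "HPco") "HPco" else c("HPco", "co")
    test_set <- subgroups$transcript_id[
      as.character(subgroups$subgroup) %in% wanted
    ]
    detected <- expression$transcript_id[
      expression$fpkm_H > 0 | expression$fpkm_P1 > 0 | expression$fpkm_P2 > 0
    ]
    test_set <- intersect(test_set, detected)
    if (length(test_set) > 0) {
      ann <- if (!is.null(ontology)) {
        propagate_annotations(annotations, ontology)
      } else {
        annotations
      }
      enrichment <- fisher_enrichment(
        test_set, detected, ann,
        filter_value = config$filter_value
      )
      enr <- enrichment[enrichment$enriched, , drop = FALSE]
      ann_level <- if (!is.null(ontology)) {
        lv <- ontology$level[enr$term_id]
        enr <- enr[!is.na(lv) & lv == config$go_level, , drop = FALSE]
        project_to_level(ann, ontology, config$go_level)
      } else {
        ann
      }
      crosstab <- crosstab_bins(
        enr[, c("term_id", "fdr")],
        fold_bins[fold_bins$transcript_id %in% test_set, ],
        ann_level
      )
    } else {
      say("  enrichment skipped: empty test set")
    }
  }

  manifest <- list(
    seed = if (!is.null(sim)) sim$config$seed else NA,
    alpha = config$alpha, min_abs_ln_ratio = config$min_abs_ln_ratio,
    pseudo_fpkm = config$pseudo_fpkm, tolerance_tau = config$tolerance_tau,
    filter_value = config$filter_value, go_level = config$go_level,
    nb_dispersion = config$nb_dispersion, enrich_set = config$enrich_set,
    n_transcripts = nrow(expression),
    n_significant_calls = sum(de_calls$significant),
    n_differential_transcripts = nrow(subgroups),
    n_hybrid_dts = nrow(hybrid),
    n_enriched_terms = if (!is.null(enrichment)) {
      sum(enrichment$enriched)
    } else {
      0L
    }
  )

  result <- list(
    expression = expression, abundance = abundance, coverage = coverage,
    de_calls = de_calls, subgroups = subgroups, actions = actions,
    action_summary = action_summary, fold_bins = fold_bins,
    enrichment = enrichment, crosstab = crosstab, sim = sim,
    manifest = manifest
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outdir
    write_tsv(expression, file.path(od, "expression.tsv"))
    write_tsv(de_calls, file.path(od, "de_calls.tsv"))
    write_tsv(subgroups, file.path(od, "subgroups.tsv"))
    write_tsv(actions, file.path(od, "gene_actions.tsv"))
    write_tsv(
      render_action_table(action_summary),
      file.path(od, "action_summary.tsv")
    )
    write_tsv(fold_bins, file.path(od, "fold_bins.tsv"))
    if (!is.null(enrichment)) {
      write_tsv(enrichment, file.path(od, "enrichment.tsv"))
    }
    if (!is.null(crosstab)) {
      write_tsv(crosstab, file.path(od, "bin_crosstab.tsv"))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  result
}

#' Render a mapping-statistics table
#'
#' Per-sample rows plus a total row, rates formatted as percentages at
#' one decimal place (half-up), mirroring the study's mapping table.
#'
#' @param samples character vector of sample names.
#' @param reads_generated,reads_mapped,reads_unique per-sample counts.
#' @param read_length read length in bp.
#' @return data frame with formatted rate columns.
#' @export
render_mapping_table <- function(samples, reads_generated, reads_mapped,
                                 reads_unique, read_length = 50) {
  st <- mapping_stats(
    c(reads_generated, sum(reads_generated)),
    c(reads_mapped, sum(reads_mapped)),
    c(reads_unique, sum(reads_unique)),
    read_length
  )
  data.frame(
    sample = c(samples, "Total"),
    reads_generated = st$reads_generated,
    reads_mapped = st$reads_mapped,
    mapping_rate = sprintf("%.1f%%", round_half_up(st$mapping_rate, 1)),
    reads_unique = st$reads_unique,
    unique_rate = sprintf("%.1f%%", round_half_up(st$unique_rate, 1)),
    stringsAsFactors = FALSE
  )
}

#' Render the gene-action summary table
#'
#' Subgroup-by-category counts with totals and a final percentage row
#' (share of the grand total per category, one decimal place).
#'
#' @param action_summary output of [summarize_actions()].
#' @return data frame in the study's layout.
#' @export
render_action_table <- function(action_summary) {
  cnt <- action_summary$counts
  cats <- GENE_ACTION_MODES
  rows <- rownames(cnt)[rownames(cnt) != "Total"]
  out <- data.frame(subgroup = c(rows, "Total"), stringsAsFactors = FALSE)
  for (cc in cats) {
    out[[cc]] <- as.character(c(cnt[rows, cc], cnt["Total", cc]))
  }
  pct_row <- data.frame(subgroup = "Percent", stringsAsFactors = FALSE)
  for (cc in cats) {
    pct_row[[cc]] <- sprintf("%.1f", action_summary$percent[[cc]])
  }
  rbind(out, pct_row)
}
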