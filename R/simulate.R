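# Synthetic three-sample study generator: gene models, planted gene-action
# modes, negative-binomial fragment counts, and planted GO enrichment.

#' Planted gene-action mode labels
#'
#' The five gene-action modes a hybrid transcript can be planted with, in
#' increasing order of hybrid expression relative to the parents:
#' underdominance (`below_low`), dominance toward the lower parent
#' (`low_parent`), additivity (`mid_parent`), dominance toward the higher
#' parent (`high_parent`) and overdominance (`above_high`).
#'
#' @export
GENE_ACTION_MODES <- c(
  "below_low", "low_parent", "mid_parent", "high_parent", "above_high"
)

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic three-sample
#' study (hybrid H and parents P1, P2).
#'
#' @param n_genes number of gene loci.
#' @param isoforms_per_gene probability vector over 1..K isoforms per gene.
#' @param mode_proportions length-5 non-negative vector over
#'   `GENE_ACTION_MODES`, summing to 1; the planted-mode mix among non-null
#'   transcripts.  The default mirrors the gene-action mix reported for the
#'   hybrid pufferfish study (742/1132/507/1042/7529 of 10,952).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   baseline transcript abundance on the FPKM scale (natural-log units).
#' @param effect_size_delta log-scale separation between the two parents
#'   and between the hybrid and the extreme parent for the
#'   overdominant/underdominant modes (natural-log units).
#' @param nb_dispersion negative-binomial dispersion phi in
#'   `variance = mu + phi * mu^2`; 0 means Poisson counts.
#' @param library_size expected total fragments per sample.
#' @param frac_null fraction of transcripts with no planted difference
#'   (H = P1 = P2 exactly).
#' @param read_length read length in bases (used only for reporting).
#' @param seed master integer seed; all stages derive deterministic
#'   substreams from it.
#' @return a list of class `"sim_config"`.
#' @examples
#' cfg <- simulation_config(n_genes = 10, seed = 1)
#' @export
simulation_config <- function(n_genes = 500,
                              isoforms_per_gene = c(1 / 3, 1 / 3, 1 / 3),
                              mode_proportions = c(
                                below_low = 742, low_parent = 1132,
                                mid_parent = 507, high_parent = 1042,
                                above_high = 7529
                              ) / 10952,
                              baseline_log_mean = 2,
                              baseline_log_sd = 1,
                              effect_size_delta = 2,
                              nb_dispersion = 0.1,
                              library_size = 1e6,
                              frac_null = 0.68,
                              read_length = 50,
                              seed = 1L) {
  stopifnot_scalar_number(n_genes, "n_genes", min = 1)
  stopifnot_scalar_number(library_size, "library_size", min = 1)
  stopifnot_scalar_number(nb_dispersion, "nb_dispersion", min = 0)
  stopifnot_scalar_number(baseline_log_mean, "baseline_log_mean")
  stopifnot_scalar_number(baseline_log_sd, "baseline_log_sd", min = 0)
  stopifnot_scalar_number(effect_size_delta, "effect_size_delta", min = 0)
  stopifnot_scalar_number(frac_null, "frac_null", min = 0)
  stopifnot_scalar_number(read_length, "read_length", min = 1)
  stopifnot_scalar_number(seed, "seed")
  if (frac_null > 1) config_error("'frac_null' must be <= 1")
  if (!is.numeric(isoforms_per_gene) || length(isoforms_per_gene) < 1 ||
    any(isoforms_per_gene < 0) ||
    abs(sum(isoforms_per_gene) - 1) > 1e-9) {
    config_error("'isoforms_per_gene' must be probabilities summing to 1")
  }
  if (!is.numeric(mode_proportions) || length(mode_proportions) != 5 ||
    any(mode_proportions < 0) ||
    abs(sum(mode_proportions) - 1) > 1e-9) {
    config_error(
      "'mode_proportions' must be 5 non-negative values summing to 1"
    )
  }
  mode_proportions <- stats::setNames(
    as.numeric(mode_proportions), GENE_ACTION_MODES
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      isoforms_per_gene = as.numeric(isoforms_per_gene),
      mode_proportions = mode_proportions,
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      effect_size_delta = effect_size_delta,
      nb_dispersion = nb_dispersion,
      library_size = library_size,
      frac_null = frac_null,
      read_length = as.integer(read_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Generate synthetic gene models
#'
#' Lays out `n_genes` loci sequentially along one chromosome; each gene
#' gets 1..K isoforms (per `isoforms_per_gene`), each transcript a small
#' number of non-overlapping exons.  Exon structure is deliberately
#' simple: only the summed exon length feeds the downstream quantification.
#' Coordinates are 0-based half-open.
#'
#' @param config a [simulation_config()] object.
#' @return data frame with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `start`, `end`.
#' @export
generate_gene_models <- function(config) {
  if (!inherits(config, "sim_config")) {
    config_error("'config' must come from simulation_config()")
  }
  with_seed(stage_seed(config$seed, "models"), {
    k_iso <- length(config$isoforms_per_gene)
    n_iso <- sample.int(k_iso, config$n_genes,
      replace = TRUE,
      prob = config$isoforms_per_gene
    )
    rows <- vector("list", sum(n_iso))
    cursor <- 0L
    t_idx <- 0L
    for (g in seq_len(config$n_genes)) {
      gene_id <- sprintf("G%05d", g)
      strand <- sample(c("+", "-"), 1L)
      gene_start <- cursor
      gene_end <- gene_start
      for (i in seq_len(n_iso[g])) {
        t_idx <- t_idx + 1L
        n_ex <- sample.int(4L, 1L)
        ex_len <- sample(seq(150L, 450L, by = 50L), n_ex, replace = TRUE)
        introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer()
        starts <- gene_start + cumsum(c(0L, ex_len[-n_ex] + introns))
        ends <- starts + ex_len
        gene_end <- max(gene_end, ends[n_ex])
        rows[[t_idx]] <- data.frame(
          transcript_id = sprintf("%s.T%d", gene_id, i),
          gene_id = gene_id,
          chrom = "chr1",
          strand = strand,
          start = starts,
          end = ends,
          stringsAsFactors = FALSE
        )
      }
      cursor <- gene_end + 1000L
    }
    models <- do.call(rbind, rows)
    rownames(models) <- NULL
    models
  })
}

#' Summed exon length per transcript
#'
#' @param models exon table as returned by [generate_gene_models()].
#' @return data frame `transcript_id`, `gene_id`, `length` (bp), one row
#'   per transcript, in first-appearance order.
#' @export
transcript_lengths <- function(models) {
  len <- tapply(models$end - models$start, models$transcript_id, sum)
  first <- !duplicated(models$transcript_id)
  out <- data.frame(
    transcript_id = models$transcript_id[first],
    gene_id = models$gene_id[first],
    stringsAsFactors = FALSE
  )
  out$length <- as.integer(len[out$transcript_id])
  if (any(out$length <= 0)) contract_error("transcript with length <= 0")
  out
}

# Hybrid mean multiplier relative to the baseline B, given parents at
# B*exp(+d/2) and B*exp(-d/2).
.mode_h_mult <- function(mode, d) {
  e <- exp(d / 2)
  switch(mode,
    below_low = exp(-d) / e,
    low_parent = 1 / e,
    mid_parent = (e + 1 / e) / 2,
    high_parent = e,
    above_high = e * exp(d),
    null = 1
  )
}

#' Plant expression levels
#'
#' Assigns every transcript a gene-action mode (`null` with probability
#' `frac_null`, otherwise per `mode_proportions`), draws log-normal
#' baseline abundances, separates the parents by `effect_size_delta`
#' (which parent is the higher one alternates, with the two sides'
#' expected fragment output balanced exactly so neither parental library
#' is systematically larger) and
#' sets the hybrid mean exactly per mode: `mid_parent` at the arithmetic
#' parental mean, `low_parent`/`high_parent` at the lower/higher parent,
#' and `above_high`/`below_low` offset by `effect_size_delta` beyond the
#' extreme parent.
#'
#' Because FPKM comparison across libraries presumes similar total
#' transcriptional output, the generator additionally equalizes the
#' expected fragment totals of the three genotypes: the baseline abundances
#' of the expansive modes (`above_high`, `high_parent`) or of the
#' repressive modes (`below_low`, `low_parent`) -- whichever side carries
#' the larger planted output shift -- are scaled by one analytically solved
#' factor.  Each transcript's (H, P1, P2) triple shares a common scale, so
#' the per-record mode invariants hold exactly.  When only one side is
#' planted (e.g. all modes overdominant) no exact balance exists; the
#' output is then anchored to the parental total and the hybrid total is
#' allowed to differ.
#'
#' @param models exon table from [generate_gene_models()].
#' @param config a [simulation_config()] object.
#' @return list with `truth` (per transcript: `transcript_id`,
#'   `planted_mode`, `true_mean_fpkm_H/P1/P2`) and `means` (the same three
#'   mean-FPKM columns keyed by transcript), scaled so each sample's
#'   expected fragment total is `library_size`.
#' @export
plant_expression <- function(models, config) {
  if (!inherits(config, "sim_config")) {
    config_error("'config' must come from simulation_config()")
  }
  tl <- transcript_lengths(models)
  if (nrow(tl) == 0) contract_error("'models' is empty")
  n <- nrow(tl)
  d <- config$effect_size_delta

  mode <- rep("null", n)
  with_seed(stage_seed(config$seed, "modes"), {
    nonnull <- which(stats::runif(n) >= config$frac_null)
    k <- length(nonnull)
    if (k > 0) {
      counts <- diff(c(0, round(cumsum(config$mode_proportions) * k)))
      mode[sample(nonnull)] <- rep(GENE_ACTION_MODES, counts)
    }
  })

  b <- numeric(n)
  side <- integer(n) # 1: P1 is the higher parent, 2: P2
  len_kb <- tl$length / 1000
  with_seed(stage_seed(config$seed, "baseline"), {
    b <- stats::rlnorm(n, config$baseline_log_mean, config$baseline_log_sd)
    for (m in GENE_ACTION_MODES) {
      idx <- which(mode == m)
      km <- length(idx)
      if (km == 0) next
      # alternate which parent is the higher one, then balance the two
      # sides' fragment mass exactly so neither parent's expected library
      # is systematically larger
      s <- rep(c(1L, 2L), length.out = km)
      side[idx] <- s
      if (km >= 2) {
        mass <- b[idx] * len_kb[idx]
        d1 <- sum(mass[s == 1L])
        d2 <- sum(mass[s == 2L])
        b[idx[s == 1L]] <- b[idx[s == 1L]] * sqrt(d2 / d1)
        b[idx[s == 2L]] <- b[idx[s == 2L]] * sqrt(d1 / d2)
      }
    }
  })
  h_mult <- vapply(mode, .mode_h_mult, numeric(1), d = d)
  pbar_mult <- ifelse(mode == "null", 1, cosh(d / 2))
  shift <- b * len_kb * (h_mult - pbar_mult) # planted output shift H - mean(P)
  excess_set <- mode %in% c("above_high", "high_parent")
  deficit_set <- mode %in% c("below_low", "low_parent")
  ex <- sum(shift[excess_set])
  df <- -sum(shift[deficit_set])
  balanced <- ex > 0 && df > 0
  if (balanced) {
    if (ex >= df) {
      b[excess_set] <- b[excess_set] * (df / ex)
    } else {
      b[deficit_set] <- b[deficit_set] * (ex / df)
    }
  }

  build <- function(b) {
    e <- exp(d / 2)
    p_hi <- b * e
    p_lo <- b / e
    p1 <- ifelse(mode == "null", b, ifelse(side == 1L, p_hi, p_lo))
    p2 <- ifelse(mode == "null", b, ifelse(side == 1L, p_lo, p_hi))
    h <- numeric(n)
    for (i in seq_len(n)) {
      h[i] <- switch(mode[i],
        null = p1[i],
        below_low = min(p1[i], p2[i]) * exp(-d),
        low_parent = min(p1[i], p2[i]),
        mid_parent = (p1[i] + p2[i]) / 2,
        high_parent = max(p1[i], p2[i]),
        above_high = max(p1[i], p2[i]) * exp(d)
      )
    }
    list(h = h, p1 = p1, p2 = p2)
  }

  v <- build(b)
  anchor <- if (balanced) {
    sum(v$h * len_kb)
  } else {
    (sum(v$p1 * len_kb) + sum(v$p2 * len_kb)) / 2
  }
  # fold the global library-size normalization into the baselines and
  # rebuild, so the per-record relations stay float-exact
  b <- b * (1e6 / anchor)
  v <- build(b)

  truth <- data.frame(
    transcript_id = tl$transcript_id,
    gene_id = tl$gene_id,
    planted_mode = mode,
    true_mean_fpkm_H = v$h,
    true_mean_fpkm_P1 = v$p1,
    true_mean_fpkm_P2 = v$p2,
    enriched_go_flag = FALSE,
    stringsAsFactors = FALSE
  )
  means <- data.frame(
    transcript_id = tl$transcript_id,
    fpkm_H = v$h,
    fpkm_P1 = v$p1,
    fpkm_P2 = v$p2,
    stringsAsFactors = FALSE
  )
  list(truth = truth, means = means)
}

#' Draw fragment counts
#'
#' Expected fragments per transcript are
#' `mean_fpkm * length_kb * library_size / 1e6`; counts are drawn
#' negative-binomial with the configured dispersion (`variance =
#' mu + phi mu^2`), or Poisson when the dispersion is zero.
#'
#' @param means mean-FPKM table from [plant_expression()] (`transcript_id`,
#'   `fpkm_H`, `fpkm_P1`, `fpkm_P2`).
#' @param models exon table (source of transcript lengths).
#' @param config a [simulation_config()] object.
#' @return data frame `transcript_id`, `gene_id`, `count_H`, `count_P1`,
#'   `count_P2`.
#' @export
sample_counts <- function(means, models, config) {
  if (!inherits(config, "sim_config")) {
    config_error("'config' must come from simulation_config()")
  }
  tl <- transcript_lengths(models)
  m <- merge(tl, means, by = "transcript_id", sort = FALSE)
  m <- m[match(tl$transcript_id, m$transcript_id), ]
  fpkm <- as.matrix(m[, c("fpkm_H", "fpkm_P1", "fpkm_P2")])
  if (any(fpkm < 0)) contract_error("negative mean FPKM")
  mu <- fpkm * (m$length / 1000) * (config$library_size / 1e6)
  phi <- config$nb_dispersion
  with_seed(stage_seed(config$seed, "counts"), {
    draw <- function(mu_col) {
      if (phi == 0) {
        stats::rpois(length(mu_col), mu_col)
      } else {
        stats::rnbinom(length(mu_col), size = 1 / phi, mu = mu_col)
      }
    }
    data.frame(
      transcript_id = m$transcript_id,
      gene_id = m$gene_id,
      count_H = draw(mu[, 1]),
      count_P1 = draw(mu[, 2]),
      count_P2 = draw(mu[, 3]),
      stringsAsFactors = FALSE
    )
  })
}

#' Plant GO annotations with known enrichment
#'
#' Every transcript is annotated to each of `n_terms` synthetic GO terms
#' with probability `background_rate`; for the designated enriched terms,
#' transcripts whose planted mode is hybrid-divergent against both parents
#' (`above_high` or `below_low`) are annotated at `enrichment_factor`
#' times the background rate instead (capped at 1).
#'
#' @param models exon table (only transcript ids are used).
#' @param truth truth table from [plant_expression()].
#' @param n_terms number of synthetic GO terms (>= 1).
#' @param enrichment_factor rate multiplier for the enriched terms
#'   (>= 1; a factor of 1 plants no enrichment).
#' @param seed integer seed.
#' @param background_rate per-term annotation probability.
#' @param n_enriched number of designated enriched terms.
#' @return list with `annotations` (two-column data frame `transcript_id`,
#'   `term_id`), `enriched_terms` (character; empty when
#'   `enrichment_factor` is 1), and `target_ids` (the hybrid-divergent
#'   transcripts the enrichment was planted on).
#' @export
plant_go_annotations <- function(models, truth, n_terms = 50,
                                 enrichment_factor = 5, seed = 1L,
                                 background_rate = 0.05, n_enriched = 3) {
  stopifnot_scalar_number(n_terms, "n_terms", min = 1)
  stopifnot_scalar_number(enrichment_factor, "enrichment_factor", min = 1)
  stopifnot_scalar_number(background_rate, "background_rate", min = 0)
  tl <- transcript_lengths(models)
  ids <- tl$transcript_id
  n <- length(ids)
  terms <- sprintf("GO:SYN%04d", seq_len(n_terms))
  n_enriched <- min(n_enriched, n_terms)
  designated <- terms[seq_len(n_enriched)]
  target <- truth$transcript_id[
    truth$planted_mode %in% c("above_high", "below_low")
  ]
  rate <- matrix(background_rate, nrow = n, ncol = n_terms)
  if (enrichment_factor > 1 && length(target) > 0 && n_enriched > 0) {
    rate[ids %in% target, seq_len(n_enriched)] <-
      min(1, enrichment_factor * background_rate)
  }
  with_seed(stage_seed(seed, "go"), {
    hit <- matrix(stats::runif(n * n_terms), n, n_terms) < rate
    idx <- which(hit, arr.ind = TRUE)
    annotations <- data.frame(
      transcript_id = ids[idx[, 1]],
      term_id = terms[idx[, 2]],
      stringsAsFactors = FALSE
    )
    annotations <- annotations[order(idx[, 1], idx[, 2]), ]
    rownames(annotations) <- NULL
    list(
      annotations = annotations,
      enriched_terms = if (enrichment_factor > 1) designated else character(),
      target_ids = target
    )
  })
}

#' Simulate a complete three-sample study
#'
#' Runs [generate_gene_models()], [plant_expression()], [sample_counts()]
#' and [plant_go_annotations()] under one master seed, optionally writing
#' all artifacts (GTF models, TSV counts/truth/annotations, JSON
#' enriched-term list) to a directory.
#'
#' @param config a [simulation_config()] object.
#' @param dir optional output directory.
#' @param n_terms,enrichment_factor,background_rate,n_enriched passed to
#'   [plant_go_annotations()].
#' @return list with `models`, `truth`, `means`, `counts`, `annotations`,
#'   `enriched_terms`, `config`.
#' @export
simulate_study <- function(config, dir = NULL, n_terms = 50,
                           enrichment_factor = 5, background_rate = 0.05,
                           n_enriched = 3) {
  models <- generate_gene_models(config)
  planted <- plant_expression(models, config)
  counts <- sample_counts(planted$means, models, config)
  go <- plant_go_annotations(models, planted$truth,
    n_terms = n_terms,
    enrichment_factor = enrichment_factor, seed = config$seed,
    background_rate = background_rate, n_enriched = n_enriched
  )
  truth <- planted$truth
  truth$enriched_go_flag <- truth$transcript_id %in%
    go$annotations$transcript_id[go$annotations$term_id %in% go$enriched_terms]
  out <- list(
    models = models, truth = truth, means = planted$means,
    counts = counts, annotations = go$annotations,
    enriched_terms = go$enriched_terms, config = config
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(models, file.path(dir, "models.gtf"))
    write_tsv(counts, file.path(dir, "counts.tsv"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
    write_tsv(go$annotations, file.path(dir, "annotations.tsv"))
    jsonlite::write_json(go$enriched_terms,
      file.path(dir, "enriched_terms.json"),
      auto_unbox = FALSE
    )
  }
  out
}
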