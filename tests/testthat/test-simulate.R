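test_that("configuration is validated field by field", {
  expect_s3_class(simulation_config(n_genes = 5, seed = 1), "sim_config")
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(library_size = 0), "library_size")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(
    simulation_config(mode_proportions = c(0.5, 0.5, 0, 0, 0.1)),
    "mode_proportions"
  )
  expect_error(
    simulation_config(isoforms_per_gene = c(0.5, 0.4)),
    "isoforms_per_gene"
  )
  expect_error(simulation_config(frac_null = 1.2), "frac_null")
})

test_that("gene models: minimal case, structure, and isoform distribution", {
  cfg1 <- simulation_config(n_genes = 1, isoforms_per_gene = 1, seed = 3)
  m1 <- generate_gene_models(cfg1)
  expect_equal(length(unique(m1$transcript_id)), 1L)

  cfg <- simulation_config(n_genes = 100, seed = 5)
  m <- generate_gene_models(cfg)
  # exons sorted and non-overlapping within each transcript
  by_t <- split(m, m$transcript_id)
  for (ex in by_t) {
    expect_true(all(ex$end > ex$start))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  expect_true(all(m$strand %in% c("+", "-")))
  # uniform isoform distribution on {1,2,3}: mean within 3 SE of 2
  n_iso <- table(transcript_lengths(m)$gene_id)
  se <- sqrt((2 / 3) / 100) # Var(U{1,2,3}) = 2/3
  expect_lt(abs(mean(n_iso) - 2), 3 * se)
})

test_that("same seed and config give byte-identical GTF output", {
  cfg <- simulation_config(n_genes = 20, seed = 11)
  f1 <- tempfile(fileext = ".gtf")
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(generate_gene_models(cfg), f1)
  write_gtf(generate_gene_models(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted means satisfy the mode relations exactly", {
  sim <- tiny_sim(seed = 9, n_genes = 200)
  tr <- sim$truth
  h <- tr$true_mean_fpkm_H
  p1 <- tr$true_mean_fpkm_P1
  p2 <- tr$true_mean_fpkm_P2
  mn <- pmin(p1, p2)
  mx <- pmax(p1, p2)
  mid <- (p1 + p2) / 2
  expect_true(all(h[tr$planted_mode == "null"] == p1[tr$planted_mode == "null"]))
  expect_true(all(p1[tr$planted_mode == "null"] == p2[tr$planted_mode == "null"]))
  expect_true(all(h[tr$planted_mode == "below_low"] < mn[tr$planted_mode == "below_low"]))
  expect_identical(
    h[tr$planted_mode == "low_parent"], mn[tr$planted_mode == "low_parent"]
  )
  expect_identical(
    h[tr$planted_mode == "mid_parent"], mid[tr$planted_mode == "mid_parent"]
  )
  expect_identical(
    h[tr$planted_mode == "high_parent"], mx[tr$planted_mode == "high_parent"]
  )
  expect_true(all(h[tr$planted_mode == "above_high"] > mx[tr$planted_mode == "above_high"]))
  # parents split by the configured log separation for every non-null mode
  nn <- tr$planted_mode != "null"
  expect_equal(
    log(mx[nn] / mn[nn]),
    rep(sim$config$effect_size_delta, sum(nn))
  )
})

test_that("frac_null = 1 plants nothing", {
  sim <- tiny_sim(seed = 2, n_genes = 50, frac_null = 1)
  expect_true(all(sim$truth$planted_mode == "null"))
  expect_true(all(sim$truth$true_mean_fpkm_H == sim$truth$true_mean_fpkm_P1))
  expect_true(all(sim$truth$true_mean_fpkm_H == sim$truth$true_mean_fpkm_P2))
})

test_that("an all-overdominant mix plants H above both parents at the planted rate", {
  cfg <- simulation_config(
    n_genes = 600, isoforms_per_gene = 1, frac_null = 0.5,
    mode_proportions = c(0, 0, 0, 0, 1), seed = 13
  )
  planted <- plant_expression(generate_gene_models(cfg), cfg)
  tr <- planted$truth
  frac_above <- mean(
    tr$true_mean_fpkm_H > pmax(tr$true_mean_fpkm_P1, tr$true_mean_fpkm_P2)
  )
  se <- sqrt(0.5 * 0.5 / nrow(tr))
  expect_lt(abs(frac_above - 0.5), 3 * se)
})

test_that("expected fragment totals equal the library size per sample", {
  cfg <- simulation_config(n_genes = 300, seed = 17)
  models <- generate_gene_models(cfg)
  means <- plant_expression(models, cfg)$means
  lk <- transcript_lengths(models)$length / 1000
  for (s in c("fpkm_H", "fpkm_P1", "fpkm_P2")) {
    expect_equal(sum(means[[s]] * lk), 1e6, tolerance = 1e-9)
  }
  # realized totals over Monte-Carlo replicates agree with the target
  reps <- 20
  totals <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    counts <- sample_counts(means, models, cfg_r)
    totals[r, ] <- c(
      sum(counts$count_H), sum(counts$count_P1), sum(counts$count_P2)
    )
  }
  for (j in 1:3) {
    se <- stats::sd(totals[, j]) / sqrt(reps)
    expect_lt(abs(mean(totals[, j]) - cfg$library_size), 3 * se)
  }
})

test_that("counts: zero mean gives zero, Poisson mean and NB variance check out", {
  cfg <- simulation_config(
    n_genes = 1, isoforms_per_gene = 1, nb_dispersion = 0, seed = 23
  )
  models <- generate_gene_models(cfg)
  means0 <- data.frame(
    transcript_id = transcript_lengths(models)$transcript_id,
    fpkm_H = 0, fpkm_P1 = 0, fpkm_P2 = 0
  )
  cnt0 <- sample_counts(means0, models, cfg)
  expect_true(all(cnt0[, c("count_H", "count_P1", "count_P2")] == 0))
  expect_error(
    sample_counts(transform(means0, fpkm_H = -1), models, cfg),
    "negative"
  )

  # expected count 100 = fpkm * len_kb * lib/1e6
  len_kb <- transcript_lengths(models)$length / 1000
  means100 <- transform(means0,
    fpkm_H = 100 / len_kb, fpkm_P1 = 100 / len_kb, fpkm_P2 = 100 / len_kb
  )
  n_draws <- 10000
  draws <- vapply(seq_len(n_draws %/% 3), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    unlist(sample_counts(means100, models, cfg_r)[, 3:5])
  }, numeric(3))
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / length(draws)))

  cfg_nb <- simulation_config(
    n_genes = 1, isoforms_per_gene = 1, nb_dispersion = 0.5, seed = 29
  )
  draws_nb <- vapply(seq_len(7000), function(r) {
    cfg_r <- cfg_nb
    cfg_r$seed <- cfg_nb$seed + r
    unlist(sample_counts(means100, models, cfg_r)[, 3:5])
  }, numeric(3))
  target_var <- 100 + 0.5 * 100^2 # mu + phi mu^2
  # SE of the sample variance: sigma^2 * sqrt((kurtosis_excess + 2)/n)
  phi <- 0.5
  mu <- 100
  r_nb <- 1 / phi
  p_nb <- r_nb / (r_nb + mu)
  kurt_ex <- 6 / r_nb + p_nb^2 / (r_nb * (1 - p_nb))
  se_var <- target_var * sqrt((kurt_ex + 2) / length(draws_nb))
  expect_lt(abs(stats::var(as.numeric(draws_nb)) - target_var), 3 * se_var)
})

test_that("planted GO annotations carry the designed enrichment", {
  sim <- tiny_sim(seed = 31, n_genes = 150)
  ann <- sim$annotations
  expect_true(all(c("transcript_id", "term_id") %in% names(ann)))
  expect_length(sim$enriched_terms, 3L)
  # planted terms annotate the hybrid-divergent transcripts at ~5x rate
  target <- sim$truth$transcript_id[
    sim$truth$planted_mode %in% c("above_high", "below_low")
  ]
  rate_in <- mean(target %in%
    ann$transcript_id[ann$term_id == sim$enriched_terms[1]])
  other <- setdiff(sim$truth$transcript_id, target)
  rate_out <- mean(other %in%
    ann$transcript_id[ann$term_id == sim$enriched_terms[1]])
  expect_gt(rate_in, rate_out)

  # factor 1 designates nothing
  go_null <- plant_go_annotations(sim$models, sim$truth,
    enrichment_factor = 1, seed = 5
  )
  expect_length(go_null$enriched_terms, 0L)

  # hypergeometric-tail oracle: background 0.05, factor 5,
  # |test| = 200, |ref \ test| = 10000 gives an astronomically small p
  p <- fisher_p_upper(50, 150, 500, 9500)
  expect_lt(p, 1e-6)
  expect_equal(p, brute_hyper_tail(50, 150, 500, 9500), tolerance = 1e-10)
})

test_that("the whole study is reproducible from the master seed", {
  s1 <- tiny_sim(seed = 77, n_genes = 40)
  s2 <- tiny_sim(seed = 77, n_genes = 40)
  expect_identical(s1$models, s2$models)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$annotations, s2$annotations)
})
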