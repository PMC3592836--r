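# Independent brute-force oracles and small fixture builders.

# Hypergeometric upper tail by direct combinatorial enumeration
# (lchoose arithmetic, independent of phyper).
brute_hyper_tail <- function(test_in, test_out, ref_in, ref_out) {
  k_annot <- test_in + ref_in
  n_test <- test_in + test_out
  n_total <- n_test + ref_in + ref_out
  ks <- seq(test_in, min(k_annot, n_test))
  if (length(ks) == 0) {
    return(0)
  }
  sum(exp(
    lchoose(k_annot, ks) + lchoose(n_total - k_annot, n_test - ks) -
      lchoose(n_total, n_test)
  ))
}

# Locus coverage by per-base tabulation (0-based half-open intervals).
brute_coverage <- function(locus_start, locus_end, starts, ends) {
  bases <- rep(FALSE, locus_end - locus_start)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], locus_start)
    hi <- min(ends[i], locus_end)
    if (hi > lo) bases[(lo - locus_start + 1):(hi - locus_start)] <- TRUE
  }
  mean(bases)
}

# Small default-structure simulation for tests.
tiny_sim <- function(seed = 42, n_genes = 60, ...) {
  simulate_study(simulation_config(n_genes = n_genes, seed = seed, ...))
}

# Published-table fixtures shipped with the package.
study_table <- function(name) {
  read_tsv(system.file("extdata", "study_tables", paste0(name, ".tsv"),
    package = "hybridaction", mustWork = TRUE
  ))
}
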