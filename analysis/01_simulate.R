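#!/usr/bin/env Rscript
# Generate the synthetic three-sample study (hybrid H, parents P1 and P2)
# used by the rest of the workflow: gene models, planted gene-action
# modes, negative-binomial fragment counts, and GO annotations with three
# planted enriched terms.  Everything downstream reads from
# results/synthetic_study/.

library(hybridaction)

out <- "results/synthetic_study"
cfg <- simulation_config(n_genes = 2000, seed = 20130308)
sim <- simulate_study(cfg, dir = out)

cat("synthetic study written to", out, "\n")
cat("transcripts:", nrow(sim$truth), " genes:", cfg$n_genes, "\n")
cat("planted modes:\n")
print(table(sim$truth$planted_mode))
cat(
  "planted enriched GO terms:",
  paste(sim$enriched_terms, collapse = ", "), "\n"
)
cat(
  "library size per sample:", cfg$library_size,
  " dispersion:", cfg$nb_dispersion,
  " parent separation (ln):", cfg$effect_size_delta, "\n"
)
cat(
  "realized totals:", sum(sim$counts$count_H), sum(sim$counts$count_P1),
  sum(sim$counts$count_P2), "\n"
)
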