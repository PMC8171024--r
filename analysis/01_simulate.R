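#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth and write
# every table (genotypes, per-site abundances, growth records, truth) to
# results/data/.

source("analysis/00_config.R")

bundle <- simulate_bundle(
  n_founders = 40, n_families = 33, sibs_per_family = 5,
  M = 3000, q = 120, sites = SITES,
  true_h2 = 0.39, true_m2 = 0.28, m2_site = "cecum", seed = SEED)

write_bundle(bundle, DATA_DIR)

cat("individuals:", nrow(bundle$genotypes),
    " SNPs:", ncol(bundle$genotypes),
    " sites:", length(bundle$abundances),
    " taxa/site:", ncol(bundle$abundances$cecum), "\n")
cat("ground truth: h2 =", bundle$truth$true_h2,
    ", m2 =", bundle$truth$true_m2, "on", bundle$truth$m2_site, "\n")
cat("written to", DATA_DIR, "\n")
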