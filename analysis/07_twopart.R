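#!/usr/bin/env Rscript
# Stage 7: which taxa track feed efficiency?  Per site: two-part model
# (presence part + log10-abundance part among present samples) on all
# taxa above 30% prevalence, plus the two extreme-group screens (ANOVA on
# RFI between top/bottom-40 abundance groups; Wilcoxon on abundance
# between top/bottom-40 RFI groups).  A taxon passing the two-part model
# and both screens at BH-adjusted p < 0.05 is called significant.

source("analysis/00_config.R")

bundle <- load_study_bundle()
truth <- jsonlite::fromJSON(file.path(DATA_DIR, "truth.json"))
phen <- compute_rfi(bundle$phenotypes[, c("id", "adfi", "adg",
                                          "bw_start", "bw_end")])
truth_taxa <- names(truth$taxon_effects)

for (s in SITES) {
  A <- bundle$abundances[[s]]
  y <- phen$rfi[match(rownames(A), phen$id)]
  tp <- two_part_association(y, A, prevalence_min = 0.30)
  eg <- extreme_group_screen(y, A, k = 40)
  merged <- merge(tp, eg, by = "taxon")
  merged$sig_all <- merged$sig_both & (merged$sig_binary | merged$sig_quant)
  write_table(merged, file.path(OUT_DIR, paste0("twopart_", s, ".tsv")),
              key = "taxon")
  n_sig <- sum(merged$sig_all, na.rm = TRUE)
  cat(sprintf("%-9s %3d taxa tested, %2d significant on all screens",
              s, nrow(merged), n_sig))
  if (s == truth$m2_site) {
    cat("  — effect site; causal taxa recovered:",
        sum(merged$taxon[merged$sig_all] %in% truth_taxa))
  }
  cat("\n")
}
cat("Causal taxa exist only in", truth$m2_site,
    "; other sites estimate the false-positive floor.\n")
share <- truth$true_m2 / max(length(truth_taxa), 1)
cat(sprintf(paste0("(m2 = %.2f spread over %d taxa gives ~%.1f%% variance",
                   " per taxon, below the\n detection limit of the",
                   " triple screen at n = 205 with 120-taxon BH\n",
                   " correction, so few or no detections are the expected",
                   " outcome here)\n"),
            truth$true_m2, length(truth_taxa), 100 * share))
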