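# Shared configuration for the analysis drivers.
#
# Study design mirrors the target experiment at desk scale: 205 birds
# (40 unrelated founders plus 33 full-sib families of 5) genotyped at
# 3,000 SNPs, microbiome profiled at 120 taxa in five gut sites, with a
# trait carrying h2 = 0.39 additive-genetic and m2 = 0.28 cecal-microbial
# variance. Every driver is deterministic given SEED.

suppressMessages(library(microFE))

SEED <- 2024L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
SITES <- c("duodenum", "jejunum", "ileum", "cecum", "feces")

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

load_study_bundle <- function() {
  cfg <- pipeline_config(
    sites = SITES, seed = SEED,
    paths = list(
      genotypes = file.path(DATA_DIR, "genotypes.tsv"),
      phenotypes = file.path(DATA_DIR, "phenotypes.csv"),
      abundances = as.list(stats::setNames(
        file.path(DATA_DIR, paste0("abundance_", SITES, ".tsv")), SITES))))
  load_dataset(cfg)
}
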