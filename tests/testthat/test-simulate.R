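test_that("unrelated founders give near-zero off-diagonal relationships", {
  g <- simulate_genotypes(n_founders = 100, M = 2000, seed = 10)
  G <- compute_grm(g$genotypes)
  off <- G[upper.tri(G)]
  # VanRaden off-diagonals for unrelated HWE founders: mean 0, SE ~ 1/sqrt(M)
  se <- 1 / sqrt(2000)
  expect_gt(mean(abs(off) <= 3 * se), 0.95)
  expect_true(all(is.na(g$pedigree$sire)))
})

test_that("full-sib pairs realize a mean VanRaden relationship near 0.5", {
  g <- simulate_genotypes(n_founders = 60, n_families = 30,
                          sibs_per_family = 4, M = 5000, seed = 11)
  G <- compute_grm(g$genotypes)
  ped <- g$pedigree
  sib_rel <- c()
  for (f in unique(stats::na.omit(ped$family))) {
    ids <- ped$id[!is.na(ped$family) & ped$family == f]
    idx <- match(ids, rownames(G))
    cm <- G[idx, idx]
    sib_rel <- c(sib_rel, cm[upper.tri(cm)])
  }
  expect_gte(length(sib_rel), 50)
  expect_gt(mean(sib_rel), 0.4)
  expect_lt(mean(sib_rel), 0.6)
})

test_that("genotype simulation is deterministic, MAF-bounded and validated", {
  g1 <- simulate_genotypes(50, 5, 3, M = 200, seed = 7)
  g2 <- simulate_genotypes(50, 5, 3, M = 200, seed = 7)
  expect_identical(g1$genotypes, g2$genotypes)
  maf <- colMeans(g1$genotypes) / 2
  expect_true(all(maf > 0 & maf <= 0.5))
  expect_error(simulate_genotypes(10, M = 20), "M < 50")
  expect_error(simulate_genotypes(10, M = 100, maf_range = c(0.01, 0.5)),
               "maf_range")
  expect_warning(simulate_genotypes(10, n_families = 2, sibs_per_family = 1,
                                    M = 100), "close-relative")
})

test_that("microbiota simulation respects closure, prevalence and SNP links", {
  A <- simulate_microbiota(50, 10, presence = 1.0, seed = 1)
  expect_true(all(A > 0))
  expect_equal(unname(rowSums(A)), rep(1, 50), tolerance = 1e-9)
  set.seed(2)
  A2 <- simulate_microbiota(400, 20, presence = 0.6, seed = 2)
  expect_lt(max(abs(colMeans(A2 > 0) - 0.6)), 0.1)
  expect_error(simulate_microbiota(10, 1), "at least 2")
})

test_that("SNP-linked taxa shift log-abundance by allele count times the shift", {
  g <- simulate_genotypes(500, M = 100, maf_range = c(0.3, 0.5), seed = 5)
  links <- data.frame(snp = "snp00001", taxon = "g__taxon001", shift = 1.0,
                      stringsAsFactors = FALSE)
  A <- simulate_microbiota(500, 10, presence = 1.0, log_sd = 1,
                           snp_links = links, genotypes = g$genotypes, seed = 6)
  # compare on the raw (pre-closure) scale via the log of relative
  # abundance: closure adds per-sample noise, so use the linked taxon's
  # log-ratio to an unlinked reference taxon
  lr <- log(A[, 1]) - log(A[, 2])
  geno <- g$genotypes[, "snp00001"]
  d20 <- mean(lr[geno == 2]) - mean(lr[geno == 0])
  expect_lt(abs(d20 - 2), 0.35)
  expect_error(
    simulate_microbiota(500, 10, snp_links = data.frame(
      snp = "nope", taxon = "g__taxon001", shift = 1),
      genotypes = g$genotypes, seed = 1),
    "absent SNP")
})

test_that("phenotype variance fractions are realized as configured", {
  g <- simulate_genotypes(2000, M = 500, seed = 20)
  ph <- simulate_phenotype(g$genotypes, NULL, true_h2 = 0.4, true_m2 = 0,
                           seed = 21)
  r2 <- summary(stats::lm(ph$phenotypes$rfi ~ ph$truth$genetic_value))$r.squared
  expect_gt(r2, 0.35)
  expect_lt(r2, 0.45)
  # pure-noise case: no causal predictor correlates with the phenotype
  ph0 <- simulate_phenotype(g$genotypes, NULL, true_h2 = 0, true_m2 = 0,
                            seed = 22)
  set.seed(23)
  some <- sample(ncol(g$genotypes), 20)
  cors <- abs(stats::cor(ph0$phenotypes$rfi, g$genotypes[, some]))
  expect_true(all(cors < 3 / sqrt(2000)))
  expect_error(simulate_phenotype(g$genotypes, NULL, true_h2 = 0.7,
                                  true_m2 = 0.5), "<= 1")
})

test_that("emitted growth records reproduce the trait through compute_rfi", {
  g <- simulate_genotypes(150, M = 200, seed = 30)
  ph <- simulate_phenotype(g$genotypes, NULL, true_h2 = 0.3, true_m2 = 0,
                           seed = 31)
  out <- compute_rfi(ph$phenotypes[, c("id", "adfi", "adg", "bw_start", "bw_end")])
  expect_equal(out$rfi, ph$phenotypes$rfi, tolerance = 1e-8)
})

test_that("bundle simulation is deterministic and carries aligned truth", {
  b1 <- simulate_bundle(n_founders = 20, n_families = 5, sibs_per_family = 4,
                        M = 100, q = 20, seed = 9)
  b2 <- simulate_bundle(n_founders = 20, n_families = 5, sibs_per_family = 4,
                        M = 100, q = 20, seed = 9)
  expect_identical(b1$genotypes, b2$genotypes)
  expect_identical(b1$abundances, b2$abundances)
  expect_identical(b1$phenotypes$rfi, b2$phenotypes$rfi)
  expect_true(all(names(b1$truth$causal_snp_effects) %in%
                    colnames(b1$genotypes)))
  expect_true(all(names(b1$truth$taxon_effects) %in%
                    colnames(b1$abundances[[b1$truth$m2_site]])))
  expect_equal(rownames(b1$abundances$cecum), b1$phenotypes$id)
})
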