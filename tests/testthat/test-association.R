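test_that("Bonferroni thresholds are exact and monotone", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 9335193), 3), 5.36e-9)
  expect_equal(signif(bonferroni_threshold(0.05, 180042), 3), 2.78e-7)
  expect_gt(bonferroni_threshold(0.05, 100), bonferroni_threshold(0.05, 200))
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("LD r2 matches the direct Pearson formula and its invariances", {
  g1 <- c(0, 1, 2, 0, 1)
  g2 <- c(0, 1, 1, 0, 2)
  # independent direct computation of squared Pearson correlation
  r <- sum((g1 - mean(g1)) * (g2 - mean(g2))) /
    sqrt(sum((g1 - mean(g1))^2) * sum((g2 - mean(g2))^2))
  expect_equal(ld_r2(g1, g2), r^2, tolerance = 1e-12)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)   # coding flip leaves r2 unchanged
  expect_error(ld_r2(g1, rep(1, 5)), "constant")
  # pairwise-complete handling of missing genotypes
  expect_equal(ld_r2(c(g1, NA), c(g2, 0)), r^2, tolerance = 1e-12)
})

test_that("effective test count collapses duplicated SNPs and keeps independent ones", {
  set.seed(1)
  M <- 40
  X <- matrix(stats::rbinom(200 * M, 2, 0.3), 200, M)
  expect_equal(effective_tests(cbind(X, X), block_size = 2 * M), M)
  # orthogonalized predictors: correlation matrix exactly identity
  Q <- qr.Q(qr(matrix(stats::rnorm(100 * 50), 100, 50)))
  expect_equal(effective_tests(Q, block_size = 50), 50)
  # direct eigen-count oracle on a mixed-LD block
  set.seed(2)
  base <- stats::rnorm(300)
  Xld <- sapply(1:10, function(i) base + stats::rnorm(300, 0, 0.33))
  Xind <- matrix(stats::rnorm(300 * 10), 300, 10)
  Xall <- cbind(Xld, Xind)
  ev <- eigen(stats::cor(Xall), symmetric = TRUE, only.values = TRUE)$values
  oracle <- which(cumsum(ev) / sum(ev) >= 0.995)[1]
  expect_equal(effective_tests(Xall, block_size = 20), oracle)
  expect_error(effective_tests(matrix(0, 3, 0)), "empty")
})

test_that("effective tests never exceed the SNP count and blocks add up", {
  set.seed(3)
  X <- matrix(stats::rbinom(100 * 60, 2, 0.4), 100, 60)
  m1 <- effective_tests(X, block_size = 20)
  expect_lte(m1, 60)
  expect_gte(m1, 1)
})

test_that("LMM GWAS reduces exactly to OLS + LR test when G is the identity", {
  set.seed(4)
  n <- 60
  X <- matrix(stats::rbinom(n * 20, 2, 0.3), n, 20)
  colnames(X) <- paste0("s", 1:20)
  y <- stats::rnorm(n) + 0.4 * X[, 3]
  G <- diag(n)
  dimnames(G) <- list(paste0("i", 1:n), paste0("i", 1:n))
  res <- suppressWarnings(lmm_gwas(y, X, G))
  for (j in 1:20) {
    f1 <- stats::lm(y ~ X[, j])
    f0 <- stats::lm(y ~ 1)
    lrt <- 2 * as.numeric(stats::logLik(f1) - stats::logLik(f0))
    p_ols <- stats::pchisq(lrt, 1, lower.tail = FALSE)
    expect_equal(res$beta[j], unname(stats::coef(f1)[2]), tolerance = 1e-6)
    expect_equal(res$p_lrt[j], p_ols, tolerance = 1e-6)
  }
})

test_that("LMM GWAS has power against a causal SNP under relatedness", {
  set.seed(5)
  ps <- replicate(10, {
    g <- simulate_genotypes(200, 50, 6, M = 300, seed = sample.int(1e6, 1))
    X <- g$genotypes
    # leave the tested SNP out of the GRM so its effect is not absorbed by
    # the polygenic term (proximal contamination; negligible at genome scale
    # but material with a few hundred markers)
    G <- compute_grm(X[, -7])
    causal <- X[, 7]
    beta <- sqrt(0.05 / stats::var(causal))
    y <- beta * causal + draw_polygenic_y(G, 0.3) * sqrt(0.95)
    lmm_gwas(y, X, G)$p_lrt[7]
  })
  expect_lt(stats::median(ps), 1e-4)
})

test_that("two-part model matches a normal-equations oracle on a toy table", {
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.8, -0.2, 1.5)
  A <- matrix(0, 8, 2, dimnames = list(paste0("s", 1:8), c("tA", "tB")))
  A[, 1] <- c(0, 0.2, 0, 0.5, 0.1, 0, 0.3, 0.4)   # prevalence 5/8
  A[, 2] <- c(0.5, 0.3, 0.6, 0.1, 0.2, 0.4, 0.3, 0.2)  # always present
  res <- two_part_association(y, A, prevalence_min = 0.3)
  # binary part slope identity: mean(y | present) - mean(y | absent)
  pres <- A[, 1] > 0
  expect_equal(res$beta_binary[res$taxon == "tA"],
               mean(y[pres]) - mean(y[!pres]), tolerance = 1e-10)
  # quantitative part: direct normal-equations + t-distribution oracle
  q <- log10(A[pres, 1])
  Xq <- cbind(1, q)
  bq <- solve(t(Xq) %*% Xq, t(Xq) %*% y[pres])
  r <- y[pres] - Xq %*% bq
  s2 <- sum(r^2) / (length(q) - 2)
  se <- sqrt(s2 * solve(t(Xq) %*% Xq)[2, 2])
  p_or <- 2 * stats::pt(abs(bq[2] / se), df = length(q) - 2, lower.tail = FALSE)
  i <- which(res$taxon == "tA")
  expect_equal(res$beta_quant[i], bq[2], tolerance = 1e-8)
  expect_equal(res$p_quant[i], p_or, tolerance = 1e-8)
  # ubiquitous taxon: binary part not estimable, quantitative still fitted
  j <- which(res$taxon == "tB")
  expect_true(is.na(res$p_binary[j]))
  expect_false(is.na(res$p_quant[j]))
  expect_error(two_part_association(rep(1, 8), A), "zero variance")
})

test_that("two-part coefficients are invariant to sample order", {
  set.seed(6)
  y <- stats::rnorm(40)
  A <- matrix(stats::rexp(40 * 5) * stats::rbinom(40 * 5, 1, 0.8), 40, 5,
              dimnames = list(paste0("s", 1:40), paste0("t", 1:5)))
  A <- A / pmax(rowSums(A), 1e-12)
  r1 <- two_part_association(y, A)
  perm <- sample(40)
  r2 <- two_part_association(y[perm], A[perm, ])
  expect_equal(r1$beta_quant, r2$beta_quant, tolerance = 1e-10)
  expect_equal(r1$p_binary, r2$p_binary, tolerance = 1e-10)
})

test_that("extreme-group screen flags a perfectly monotone taxon and not null taxa", {
  set.seed(7)
  n <- 200
  y <- stats::rnorm(n)
  A <- matrix(stats::runif(n * 10, 0.01, 1), n, 10)
  A[, 1] <- rank(y) / n            # strictly monotone in y
  colnames(A) <- paste0("t", 1:10)
  rownames(A) <- paste0("s", 1:n)
  eg <- extreme_group_screen(y, A, k = 40)
  expect_true(eg$sig_both[1])
  tp <- two_part_association(y, A)
  expect_true(tp$sig_quant[tp$taxon == "t1"])
  # null taxa essentially never pass all screens
  expect_lte(sum(eg$sig_both[-1]), 1)
  expect_error(extreme_group_screen(y, A, k = 150), "2k")
})

test_that("genotype-group screen detects linked taxa and handles degenerate splits", {
  set.seed(8)
  g <- simulate_genotypes(300, M = 60, maf_range = c(0.2, 0.5), seed = 8)
  links <- data.frame(snp = "snp00005", taxon = "g__taxon002", shift = 1.5)
  A <- simulate_microbiota(300, 12, presence = 0.9, snp_links = links,
                           genotypes = g$genotypes, seed = 9)
  res <- genotype_group_screen("snp00005", g$genotypes, A)
  expect_lt(res$p_adj[res$taxon == "g__taxon002"], 0.05)
  # calibration: unlinked taxa reject at roughly the nominal rate
  expect_lt(mean(res$p[res$taxon != "g__taxon002"] < 0.05), 0.4)
  # single-carrier split still runs, flagged low power
  X <- g$genotypes
  X[, 1] <- c(1, rep(0, 299))
  res2 <- genotype_group_screen("snp00001", X, A)
  expect_true(all(res2$low_power))
  expect_equal(unique(res2$n_other), 1)
  expect_message(genotype_group_screen("snp00002", 0 * X, A), "monomorphic")
})
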