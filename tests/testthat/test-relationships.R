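test_that("GRM matches the VanRaden formula on a hand-computed toy", {
  X <- rbind(c(0, 2), c(1, 1), c(2, 0))
  rownames(X) <- c("a", "b", "c")
  G <- compute_grm(X)
  # p = (0.5, 0.5); Z rows (-1,1), (0,0), (1,-1); 2*sum p(1-p) = 1
  Z <- rbind(c(-1, 1), c(0, 0), c(1, -1))
  expected <- Z %*% t(Z) / (2 * sum(0.5 * 0.5 * 2))
  expect_equal(unclass(G), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rownames(G), c("a", "b", "c"))
})

test_that("GRM: duplicate genotype rows and SNP-order invariance", {
  set.seed(1)
  X <- matrix(rbinom(6 * 100, 2, 0.3), 6, 100)
  X[2, ] <- X[1, ]
  rownames(X) <- paste0("i", 1:6)
  G <- compute_grm(X)
  expect_equal(G[1, 2], G[1, 1], tolerance = 1e-10)
  expect_equal(G[1, 2], G[2, 2], tolerance = 1e-10)
  G2 <- compute_grm(X[, sample(ncol(X))])
  expect_equal(unclass(G), unclass(G2), tolerance = 1e-12)
  expect_error(compute_grm(matrix(1, 4, 5)), "polymorphic")
})

test_that("GRM diagonal averages 1 under Hardy-Weinberg founders", {
  set.seed(2)
  g <- simulate_genotypes(n_founders = 300, M = 3000, seed = 2)
  G <- compute_grm(g$genotypes)
  dbar <- mean(diag(G))
  se <- stats::sd(diag(G)) / sqrt(nrow(G))
  expect_lt(abs(dbar - 1), 3 * se + 0.02)
  # PSD within tolerance
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("MRM matches the direct standardized-log formula and its trace identity", {
  A <- rbind(c(0.5, 0.5), c(0.3, 0.7), c(0.8, 0.2))
  rownames(A) <- paste0("s", 1:3)
  M <- compute_mrm(A, pseudocount = 0.01)
  S <- scale(log10(A + 0.01))
  expect_equal(unclass(M), unname(S %*% t(S) / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  n <- nrow(A)
  expect_equal(sum(diag(M)) / n, (n - 1) / n, tolerance = 1e-10)
  # duplicate profiles give equal rows
  A2 <- rbind(A, A[1, , drop = FALSE])
  rownames(A2) <- paste0("s", 1:4)
  M2 <- compute_mrm(A2, pseudocount = 0.01)
  expect_equal(M2[4, ], M2[1, ], tolerance = 1e-12)
})

test_that("MRM is invariant to global rescaling before renormalization", {
  set.seed(3)
  A <- matrix(stats::rexp(10 * 8), 10, 8)
  A <- A / rowSums(A)
  dimnames(A) <- list(paste0("s", 1:10), paste0("t", 1:8))
  # scaling all raw abundances by a constant then renormalizing is a no-op
  # on proportions; the adaptive pseudocount keeps the log-transform stable
  B <- (A * 1000) / rowSums(A * 1000)
  expect_equal(unclass(compute_mrm(A)), unclass(compute_mrm(B)),
               tolerance = 1e-10)
})

test_that("Bray-Curtis matches the hand formula and its boundary cases", {
  A <- rbind(x = c(2, 1, 0), y = c(1, 1, 1), z = c(0, 0, 5))
  colnames(A) <- paste0("t", 1:3)
  D <- bray_curtis_matrix(A, as_similarity = FALSE)
  expect_equal(D["x", "y"], 2 / 6, tolerance = 1e-12)
  expect_equal(D["x", "x"], 0)
  expect_equal(D["x", "z"], 1)           # disjoint supports
  S <- bray_curtis_matrix(A)
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_true(all(S >= 0 & S <= 1))
  expect_error(bray_curtis_matrix(rbind(c(1, 1), c(0, 0))), "all-zero")
})

test_that("pair classification respects the kinship strata thresholds", {
  K <- matrix(c(1, 0.04, 0.07, 0.04, 1, 0.25, 0.07, 0.25, 1), 3)
  dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ps <- classify_relative_pairs(K)
  expect_equal(nrow(ps), 3)
  expect_equal(ps$stratum[ps$id_i == "a" & ps$id_j == "b"], "distant")
  expect_equal(ps$stratum[ps$id_i == "a" & ps$id_j == "c"], "intermediate")
  expect_equal(ps$stratum[ps$id_i == "b" & ps$id_j == "c"], "close")
  # boundary values are included in their strata (<= 0.05, >= 0.10)
  K2 <- matrix(c(1, 0.05, 0.05, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(classify_relative_pairs(K2)$stratum, "distant")
  expect_error(classify_relative_pairs(K, distant_max = 0.2, close_min = 0.1),
               "distant_max")
})

test_that("205 individuals yield 20910 unordered pairs", {
  K <- diag(205)
  dimnames(K) <- list(paste0("i", 1:205), paste0("i", 1:205))
  expect_equal(nrow(classify_relative_pairs(K)), 20910)
})
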