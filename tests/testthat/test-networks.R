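test_that("prevalence filter applies each criterion and reports no-ops", {
  set.seed(1)
  A <- matrix(stats::runif(100 * 4), 100, 4,
              dimnames = list(paste0("s", 1:100), paste0("t", 1:4)))
  A[sample(100, 6), 2] <- 0          # detection 94%
  A[2:100, 3] <- 0                   # detected in exactly 1 sample
  out <- suppressMessages(prevalence_filter(A, min_prevalence = 0.95))
  expect_false("t2" %in% colnames(out))
  expect_true("t1" %in% colnames(out))
  out2 <- suppressMessages(prevalence_filter(A, min_samples = 2))
  expect_false("t3" %in% colnames(out2))
  out3 <- suppressMessages(prevalence_filter(A))
  expect_equal(out3, A)
  expect_error(suppressMessages(prevalence_filter(A, min_prevalence = 1.5)),
               "min_prevalence")
  expect_error(suppressMessages(
    prevalence_filter(A, min_mean_abundance = 10)), "survive")
})

test_that("perfectly correlated taxa produce one positive edge with r = 1", {
  set.seed(2)
  base <- stats::runif(50, 0.1, 1)
  A <- cbind(t1 = base, t2 = 2 * base, t3 = stats::runif(50, 0.1, 1))
  rownames(A) <- paste0("s", 1:50)
  net <- cooccurrence_network(A, pseudocount = 0)
  edge <- net[net$taxon_a == "t1" & net$taxon_b == "t2", ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$r_pearson, 1, tolerance = 1e-10)
  expect_equal(edge$r_spearman, 1, tolerance = 1e-10)
  expect_equal(edge$sign, "positive")
})

test_that("network edges match a brute-force correlation + BH oracle", {
  set.seed(3)
  n <- 60
  c1 <- stats::rnorm(n)
  A <- exp(cbind(
    c1 + stats::rnorm(n, 0, 0.4), c1 + stats::rnorm(n, 0, 0.4),
    c1 + stats::rnorm(n, 0, 0.4), -c1 + stats::rnorm(n, 0, 0.4),
    -c1 + stats::rnorm(n, 0, 0.4), -c1 + stats::rnorm(n, 0, 0.4)
  ))
  A <- A / rowSums(A)
  dimnames(A) <- list(paste0("s", 1:n), paste0("t", 1:6))
  pc <- min(A[A > 0]) / 2
  net <- cooccurrence_network(A, pseudocount = pc)
  # brute-force oracle over all 15 pairs
  L <- log10(A + pc)
  pairs <- t(utils::combn(6, 2))
  ora <- data.frame(
    a = colnames(A)[pairs[, 1]], b = colnames(A)[pairs[, 2]],
    rp = NA_real_, rs = NA_real_, pp = NA_real_, ps = NA_real_)
  for (i in seq_len(15)) {
    x <- L[, pairs[i, 1]]; y <- L[, pairs[i, 2]]
    ora$rp[i] <- stats::cor(x, y)
    ora$rs[i] <- stats::cor(x, y, method = "spearman")
    tfun <- function(r) 2 * stats::pt(abs(r) * sqrt((n - 2) / (1 - r^2)),
                                      n - 2, lower.tail = FALSE)
    ora$pp[i] <- tfun(ora$rp[i]); ora$ps[i] <- tfun(ora$rs[i])
  }
  ora$pp_adj <- bh_oracle(ora$pp); ora$ps_adj <- bh_oracle(ora$ps)
  keep <- abs(ora$rp) > 0.3 & ora$pp_adj < 0.05 &
    abs(ora$rs) > 0.3 & ora$ps_adj < 0.05
  expected <- sort(paste(ora$a[keep], ora$b[keep]))
  expect_equal(sort(paste(net$taxon_a, net$taxon_b)), expected)
  # permuting samples leaves the edge set unchanged
  net_p <- cooccurrence_network(A[sample(n), ], pseudocount = pc)
  expect_equal(net_p[, c("taxon_a", "taxon_b")], net[, c("taxon_a", "taxon_b")])
})

test_that("independent taxa yield essentially empty networks", {
  set.seed(4)
  spurious <- replicate(20, {
    A <- matrix(stats::rexp(200 * 20), 200, 20)
    A <- A / rowSums(A)
    dimnames(A) <- list(paste0("s", 1:200), paste0("t", 1:20))
    nrow(cooccurrence_network(A))
  })
  expect_lte(mean(spurious), 1)
  expect_error(cooccurrence_network(matrix(1, 5, 2)), "at least 3")
})

test_that("aggregate correlation sums groups correctly and matches a direct oracle", {
  A <- toy_abundance()
  gm <- c(t1 = "A", t2 = "A", t3 = "B", t4 = "B")
  res <- aggregate_correlation(A, gm, "A", "B")
  xa <- A[, "t1"] + A[, "t2"]
  xb <- A[, "t3"] + A[, "t4"]
  r_direct <- sum((xa - mean(xa)) * (xb - mean(xb))) /
    sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
  expect_equal(res$r, r_direct, tolerance = 1e-10)
  # compositional closure: the two aggregates account for everything
  expect_equal(unname(xa + xb), rep(1, 4), tolerance = 1e-12)
  # singleton group equals its member taxon
  gm2 <- c(t1 = "solo", t2 = "rest", t3 = "rest", t4 = "rest")
  res2 <- aggregate_correlation(A, gm2, "solo", "rest", method = "spearman")
  expect_true(is.finite(res2$r))
  expect_error(aggregate_correlation(A, gm, "A", "Z"), "unknown")
})
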