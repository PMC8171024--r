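#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Composite LD r-squared between two SNPs
#'
#' Squared Pearson correlation of additive genotype counts, computed on
#' pairwise-complete observations.
#'
#' @param g1,g2 genotype vectors (0/1/2, NAs allowed), same length.
#' @return scalar r^2 in [0, 1].
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("genotype vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) {
    stop("constant genotype vector; r2 undefined")
  }
  stats::cor(g1, g2)^2
}

#' Effective number of independent tests (simpleM)
#'
#' For each consecutive non-overlapping block of SNPs, eigendecompose the
#' SNP-SNP correlation matrix and count the smallest number of leading
#' eigenvalues whose sum reaches \code{variance_fraction} of the total;
#' the effective test count is the sum over blocks.
#'
#' @param X genotype matrix (individuals x SNPs), no missing values.
#' @param variance_fraction fraction of variance to capture (default 0.995).
#' @param block_size SNPs per block (default 1000).
#' @return integer M_eff.
#' @export
effective_tests <- function(X, variance_fraction = 0.995, block_size = 1000) {
  if (block_size < 2) stop("block_size must be >= 2")
  X <- as.matrix(X)
  M <- ncol(X)
  if (M == 0) stop("empty genotype set")
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  M <- ncol(X)
  if (M == 0) stop("no polymorphic SNPs")
  starts <- seq(1, M, by = block_size)
  m_eff <- 0L
  for (s in starts) {
    block <- X[, s:min(s + block_size - 1, M), drop = FALSE]
    if (ncol(block) == 1) { m_eff <- m_eff + 1L; next }
    ev <- eigen(stats::cor(block), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    m_eff <- m_eff + which(cumsum(ev) / sum(ev) >= variance_fraction)[1]
  }
  as.integer(m_eff)
}

#' Mixed-model association scan across SNPs
#'
#' Model per SNP: y = Q alpha + x beta + g + e with g ~ N(0, G sigma2_g).
#' The variance ratio is estimated once under the null (no SNP) by
#' \code{\link{reml_fit}} and reused for every marker; each SNP is then
#' tested by generalized least squares in the eigen-rotated coordinates,
#' with a likelihood-ratio p-value against chi-squared(1). When G is the
#' identity this reduces exactly to OLS plus a likelihood-ratio test.
#'
#' @param y trait vector.
#' @param X genotype matrix (individuals x SNPs, 0/1/2, no missing).
#' @param G genomic \code{relationship_matrix}.
#' @param Q covariate matrix with intercept (default intercept only).
#' @param sig_threshold,sugg_threshold p-value cutoffs for the
#'   \code{tier} column; defaults: Bonferroni 0.05/M and no suggestive
#'   tier.
#' @param null_fit optional precomputed \code{\link{reml_fit}} on (y, G, Q).
#' @return data.frame with one row per polymorphic SNP: \code{snp},
#'   \code{maf}, \code{beta}, \code{se}, \code{p_lrt}, \code{tier};
#'   constant SNPs are skipped (message records how many).
#' @export
lmm_gwas <- function(y, X, G, Q = NULL,
                     sig_threshold = bonferroni_threshold(0.05, ncol(X)),
                     sugg_threshold = NULL, null_fit = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  Q <- as.matrix(Q)
  keep <- apply(X, 2, stats::sd) > 0
  if (any(!keep)) message("skipping ", sum(!keep), " constant SNP(s)")
  X <- X[, keep, drop = FALSE]
  if (is.null(null_fit)) null_fit <- reml_fit(y, G, Q)
  h <- null_fit$ratio
  d <- null_fit$eigen_values
  U <- null_fit$eigen_vectors
  w <- 1 / (h * d + (1 - h))
  sw <- sqrt(w)
  ys <- sw * as.vector(crossprod(U, y))
  Qs <- sw * crossprod(U, Q)
  Xs <- sw * crossprod(U, X)
  # residualize trait and every SNP on the covariates under the GLS metric
  qrQ <- qr(Qs)
  ry <- qr.resid(qrQ, ys)
  rX <- qr.resid(qrQ, Xs)
  rss0 <- sum(ry^2)
  xtx <- colSums(rX^2)
  xty <- colSums(rX * ry)
  beta <- xty / xtx
  rss1 <- rss0 - xty^2 / xtx
  rss1 <- pmax(rss1, .Machine$double.eps)
  df_res <- n - ncol(Q) - 1
  se <- sqrt(rss1 / df_res / xtx)
  lrt <- n * log(rss0 / rss1)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  tier <- rep("none", ncol(X))
  if (!is.null(sugg_threshold)) tier[p < sugg_threshold] <- "suggestive"
  tier[p < sig_threshold] <- "genome-wide"
  data.frame(
    snp = colnames(X),
    maf = pmin(colMeans(X) / 2, 1 - colMeans(X) / 2),
    beta = beta, se = se, p_lrt = p, tier = tier,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Two-part association between taxa and a phenotype
#'
#' For every taxon detected in more than \code{prevalence_min} of samples:
#' a binary part regressing the phenotype on the presence indicator
#' (0/1, with intercept; its slope is the present-vs-absent mean
#' difference), and a quantitative part regressing the phenotype on the
#' log10 relative abundance using only the samples where the taxon is
#' present. BH adjustment is applied separately within each part.
#'
#' @param y phenotype vector aligned with the rows of \code{A}.
#' @param A samples x taxa relative abundance matrix.
#' @param prevalence_min minimum detection rate for a taxon to be tested
#'   (default 0.30, strict inequality).
#' @param p_cut adjusted-p cutoff for the significance flags (default 0.05).
#' @return data.frame per retained taxon: \code{taxon}, \code{prevalence},
#'   \code{beta_binary}, \code{p_binary}, \code{beta_quant},
#'   \code{p_quant}, \code{p_adj_binary}, \code{p_adj_quant},
#'   \code{sig_binary}, \code{sig_quant}. The binary part is NA when the
#'   taxon is present in every sample (constant predictor).
#' @export
two_part_association <- function(y, A, prevalence_min = 0.30, p_cut = 0.05) {
  A <- as.matrix(A)
  if (length(y) != nrow(A)) stop("y and abundance rows are not aligned")
  if (stats::var(y) == 0) stop("phenotype has zero variance")
  prev <- colMeans(A > 0)
  keep <- which(prev > prevalence_min)
  if (length(keep) == 0) stop("no taxon passes the prevalence filter")
  one <- function(j) {
    a <- A[, j]
    b <- as.numeric(a > 0)
    if (stats::var(b) > 0) {
      fb <- summary(stats::lm(y ~ b))$coefficients
      bb <- fb["b", "Estimate"]; pb <- fb["b", "Pr(>|t|)"]
    } else {
      bb <- NA_real_; pb <- NA_real_
    }
    pres <- a > 0
    if (sum(pres) >= 3 && stats::var(log10(a[pres])) > 0) {
      q <- log10(a[pres])
      fq <- summary(stats::lm(y[pres] ~ q))$coefficients
      bq <- fq["q", "Estimate"]; pq <- fq["q", "Pr(>|t|)"]
    } else {
      bq <- NA_real_; pq <- NA_real_
    }
    c(bb, pb, bq, pq)
  }
  res <- vapply(keep, one, numeric(4))
  out <- data.frame(
    taxon = colnames(A)[keep],
    prevalence = prev[keep],
    beta_binary = res[1, ], p_binary = res[2, ],
    beta_quant = res[3, ], p_quant = res[4, ],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p_adj_binary <- bh_adjust(out$p_binary)
  out$p_adj_quant <- bh_adjust(out$p_quant)
  out$sig_binary <- !is.na(out$p_adj_binary) & out$p_adj_binary < p_cut
  out$sig_quant <- !is.na(out$p_adj_quant) & out$p_adj_quant < p_cut
  out
}

#' Extreme-group screens of taxa against a phenotype
#'
#' Two complementary tests per taxon: (i) ANOVA on the phenotype between
#' the k samples with the highest and the k with the lowest abundance of
#' the taxon; (ii) Wilcoxon rank-sum on the taxon abundance between the k
#' samples with the highest and lowest phenotype values. Each family of
#' p-values is BH-adjusted. Combined with the two-part model, a taxon is
#' called significant when all adjusted p-values fall below \code{p_cut}.
#' Ranks are tie-broken by sample order, so results are deterministic.
#'
#' @param y phenotype vector aligned with rows of \code{A}.
#' @param A samples x taxa abundance matrix.
#' @param k extreme-group size (default 40); needs \code{2k <= n}.
#' @param p_cut adjusted-p cutoff for the significance flags.
#' @return data.frame per taxon: \code{taxon}, \code{anova_p},
#'   \code{anova_p_adj}, \code{wilcoxon_p}, \code{wilcoxon_p_adj},
#'   \code{sig_both}.
#' @export
extreme_group_screen <- function(y, A, k = 40, p_cut = 0.05) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n < 2 * k) stop("need at least 2k = ", 2 * k, " samples, have ", n)
  ord_y <- order(y, seq_len(n))
  low_y <- ord_y[seq_len(k)]
  high_y <- ord_y[(n - k + 1):n]
  res <- t(vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]
    ord_a <- order(a, seq_len(n))
    low_a <- ord_a[seq_len(k)]
    high_a <- ord_a[(n - k + 1):n]
    pa <- tryCatch(
      one_way_anova_tukey(list(low = y[low_a], high = y[high_a]))$p_raw,
      error = function(e) NA_real_)
    pw <- tryCatch(
      wilcoxon_rank_sum(a[high_y], a[low_y])$p_raw,
      error = function(e) NA_real_)
    c(pa, pw)
  }, numeric(2)))
  out <- data.frame(
    taxon = colnames(A), anova_p = res[, 1], wilcoxon_p = res[, 2],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$anova_p_adj <- bh_adjust(out$anova_p)
  out$wilcoxon_p_adj <- bh_adjust(out$wilcoxon_p)
  out$sig_both <- !is.na(out$anova_p_adj) & !is.na(out$wilcoxon_p_adj) &
    out$anova_p_adj < p_cut & out$wilcoxon_p_adj < p_cut
  out
}

#' Genotype-group screen of taxa at chosen SNPs
#'
#' For each SNP, Wilcoxon rank-sum on each taxon's abundance between
#' major-allele homozygotes and carriers of the minor allele, BH-adjusted
#' within SNP. With minor-allele coding the major homozygote class is
#' genotype 0.
#'
#' @param snp_ids SNP identifiers to screen (columns of \code{X}).
#' @param X genotype matrix (individuals x SNPs, minor-allele counts).
#' @param A samples x taxa abundance matrix aligned with rows of \code{X}.
#' @return data.frame per (snp, taxon): \code{snp}, \code{taxon},
#'   \code{n_major}, \code{n_other}, \code{p}, \code{p_adj},
#'   \code{low_power} (TRUE when either group has < 5 samples).
#'   Monomorphic SNPs are skipped with a message.
#' @export
genotype_group_screen <- function(snp_ids, X, A) {
  A <- as.matrix(A)
  out <- list()
  for (s in snp_ids) {
    if (!s %in% colnames(X)) stop("unknown SNP: ", s)
    g <- X[, s]
    major <- g == 0
    if (all(major) || !any(major)) {
      message("skipping monomorphic split for SNP ", s)
      next
    }
    p <- vapply(seq_len(ncol(A)), function(j) {
      tryCatch(wilcoxon_rank_sum(A[major, j], A[!major, j])$p_raw,
               error = function(e) NA_real_)
    }, 0)
    out[[s]] <- data.frame(
      snp = s, taxon = colnames(A),
      n_major = sum(major), n_other = sum(!major),
      p = p, p_adj = bh_adjust(p),
      low_power = min(sum(major), sum(!major)) < 5,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  if (length(out) == 0) {
    return(data.frame(snp = character(), taxon = character(),
                      n_major = integer(), n_other = integer(),
                      p = numeric(), p_adj = numeric(),
                      low_power = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
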