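#' Filter taxa by prevalence and mean abundance
#'
#' Removes taxa failing any active criterion: detection rate below
#' \code{min_prevalence}, mean relative abundance at or below
#' \code{min_mean_abundance}, or detected in fewer than \code{min_samples}
#' samples. Thresholds of zero deactivate a criterion.
#'
#' @param A samples x taxa abundance matrix.
#' @param min_prevalence minimum detection rate in [0, 1].
#' @param min_mean_abundance taxa must exceed this mean relative abundance.
#' @param min_samples minimum number of samples with nonzero abundance.
#' @return filtered abundance matrix (same rows, fewer columns), with a
#'   message recording counts in/out.
#' @export
prevalence_filter <- function(A, min_prevalence = 0, min_mean_abundance = 0,
                              min_samples = 0) {
  if (min_prevalence < 0 || min_prevalence > 1) stop("min_prevalence must be in [0, 1]")
  A <- as.matrix(A)
  det <- colSums(A > 0)
  keep <- (det / nrow(A)) >= min_prevalence &
    colMeans(A) > min_mean_abundance &
    det >= min_samples
  if (!any(keep)) stop("no taxa survive the filter")
  message("prevalence_filter: ", sum(keep), " of ", ncol(A), " taxa retained")
  A[, keep, drop = FALSE]
}

#' Taxon co-occurrence network
#'
#' Relative abundances are log10-transformed (shared pseudocount, half the
#' minimum nonzero value); all pairwise Pearson and Spearman correlations
#' are computed with t-approximation p-values, BH-adjusted within each
#' method. An edge is kept when |r| > \code{r_cut} and adjusted p <
#' \code{p_cut} for both methods (default) or for either one.
#'
#' @param A samples x taxa abundance matrix, already prevalence-filtered.
#' @param r_cut absolute correlation cutoff (default 0.3, strict).
#' @param p_cut adjusted-p cutoff (default 0.05).
#' @param require_both_methods if TRUE (default) both Pearson and Spearman
#'   must pass; if FALSE either suffices.
#' @param pseudocount added before log10.
#' @return data.frame of edges: \code{taxon_a} < \code{taxon_b} by label,
#'   \code{r_pearson}, \code{r_spearman}, \code{p_adj_pearson},
#'   \code{p_adj_spearman}, \code{sign}.
#' @export
cooccurrence_network <- function(A, r_cut = 0.3, p_cut = 0.05,
                                 require_both_methods = TRUE,
                                 pseudocount = abundance_pseudocount(A)) {
  A <- as.matrix(A)
  q <- ncol(A)
  n <- nrow(A)
  if (q < 3) stop("need at least 3 taxa for a network")
  L <- log10(A + pseudocount)
  cor_p <- function(R) {
    r <- R[upper.tri(R)]
    r2 <- pmin(r^2, 1 - 1e-15)
    tt <- abs(r) * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  }
  Rp <- stats::cor(L)
  Rs <- stats::cor(L, method = "spearman")
  idx <- which(upper.tri(Rp), arr.ind = TRUE)
  rp <- Rp[upper.tri(Rp)]
  rs <- Rs[upper.tri(Rs)]
  padj_p <- bh_adjust(cor_p(Rp))
  padj_s <- bh_adjust(cor_p(Rs))
  pass_p <- abs(rp) > r_cut & padj_p < p_cut
  pass_s <- abs(rs) > r_cut & padj_s < p_cut
  keep <- if (require_both_methods) pass_p & pass_s else pass_p | pass_s
  lab <- colnames(L)
  a <- lab[idx[, 1]]; b <- lab[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(
    taxon_a = a[keep], taxon_b = b[keep],
    r_pearson = rp[keep], r_spearman = rs[keep],
    p_adj_pearson = padj_p[keep], p_adj_spearman = padj_s[keep],
    sign = ifelse(rp[keep] + rs[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}

#' Correlation between two taxon-group aggregates
#'
#' Sums relative abundances per sample within each group (e.g. all genera
#' of one order) and correlates the two group totals across samples.
#'
#' @param A samples x taxa abundance matrix.
#' @param group_map named character vector mapping taxon -> group label.
#' @param group_a,group_b the two group labels to correlate.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return list with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
aggregate_correlation <- function(A, group_map, group_a, group_b,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  A <- as.matrix(A)
  sum_group <- function(g) {
    members <- names(group_map)[group_map == g]
    members <- intersect(members, colnames(A))
    if (length(members) == 0) stop("unknown or empty group: ", g)
    rowSums(A[, members, drop = FALSE])
  }
  xa <- sum_group(group_a)
  xb <- sum_group(group_b)
  ct <- stats::cor.test(xa, xb, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xa), method = method)
}
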