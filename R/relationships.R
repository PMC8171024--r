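#' @title Relationship matrices
#' @description Constructors for the three labeled symmetric similarity
#'   matrices the analysis uses: the genomic relationship matrix (GRM,
#'   VanRaden method 1), the microbial relationship matrix (MRM, from
#'   standardized log abundances), and Bray-Curtis similarity.
#' @name relationships
NULL

new_relationship_matrix <- function(values, kind) {
  stopifnot(kind %in% c("genomic", "microbial", "bray_curtis_similarity",
                        "bray_curtis_dissimilarity"))
  values <- (values + t(values)) / 2   # enforce exact symmetry
  structure(values, kind = kind, class = c("relationship_matrix", "matrix", "array"))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' G = Z Z' / (2 * sum p (1 - p)) with Z = X - 2p, where X is the n x M
#' matrix of minor-allele counts and p the per-SNP allele frequency
#' estimated from X. Missing genotypes must already be imputed.
#'
#' @param X numeric matrix, individuals x SNPs, additive coding 0/1/2
#'   (rownames = individual ids).
#' @return n x n \code{relationship_matrix} of kind \code{"genomic"}.
#' @export
compute_grm <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("genotypes contain missing values; mean-impute first")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1 & apply(X, 2, stats::var) > 0
  if (sum(poly) < 2) stop("fewer than 2 polymorphic SNPs")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(X), rownames(X))
  new_relationship_matrix(G, "genomic")
}

#' Pseudocount for log-transforming relative abundances
#'
#' Half the smallest nonzero value in the table; scale-adaptive so the
#' transform is invariant to a global rescaling followed by renormalization.
#'
#' @param A abundance matrix (samples x taxa), non-negative.
#' @return scalar pseudocount.
#' @export
abundance_pseudocount <- function(A) {
  nz <- A[A > 0]
  if (length(nz) == 0) stop("abundance table is all zero")
  min(nz) / 2
}

#' Microbial relationship matrix
#'
#' Per-taxon log10(abundance + pseudocount), column-standardized to zero
#' mean and unit (sample, n-1 denominator) variance; taxa with zero variance
#' are dropped. M = S S' / q over the q retained taxa.
#'
#' @param A abundance matrix, samples x taxa, relative abundances
#'   (rownames = sample ids).
#' @param pseudocount added before log10; default half the smallest nonzero
#'   abundance (see \code{\link{abundance_pseudocount}}).
#' @return n x n \code{relationship_matrix} of kind \code{"microbial"}.
#' @export
compute_mrm <- function(A, pseudocount = abundance_pseudocount(A)) {
  A <- as.matrix(A)
  if (ncol(A) < 2) stop("need at least 2 taxa")
  L <- log10(A + pseudocount)
  v <- apply(L, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all taxa have zero variance on the log scale")
  S <- scale(L[, keep, drop = FALSE])
  M <- tcrossprod(S) / sum(keep)
  dimnames(M) <- list(rownames(A), rownames(A))
  new_relationship_matrix(M, "microbial")
}

#' Bray-Curtis dissimilarity or similarity matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i); similarity is 1 - BC.
#'
#' @param A abundance matrix, samples x taxa, non-negative.
#' @param as_similarity return 1 - BC (default) rather than BC.
#' @return n x n \code{relationship_matrix} of kind
#'   \code{"bray_curtis_similarity"} (or \code{"..._dissimilarity"}).
#' @export
bray_curtis_matrix <- function(A, as_similarity = TRUE) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("abundances must be non-negative")
  zero_rows <- rowSums(A) == 0
  if (any(zero_rows)) {
    stop("sample(s) with all-zero abundances: ",
         paste(rownames(A)[zero_rows], collapse = ", "))
  }
  D <- as.matrix(vegan::vegdist(A, method = "bray"))
  dimnames(D) <- list(rownames(A), rownames(A))
  if (as_similarity) {
    new_relationship_matrix(1 - D, "bray_curtis_similarity")
  } else {
    new_relationship_matrix(D, "bray_curtis_dissimilarity")
  }
}

#' Classify unordered pairs into kinship strata
#'
#' Pairs with kinship at most \code{distant_max} are "distant" relatives,
#' pairs with kinship at least \code{close_min} are "close", anything in
#' between is "intermediate" and excluded from both strata.
#'
#' @param K genomic \code{relationship_matrix}.
#' @param distant_max upper kinship bound for the distant stratum (default 0.05).
#' @param close_min lower kinship bound for the close stratum (default 0.10).
#' @return data.frame with one row per unordered pair: \code{id_i},
#'   \code{id_j} (i before j in label order), \code{kinship},
#'   \code{stratum}.
#' @export
classify_relative_pairs <- function(K, distant_max = 0.05, close_min = 0.10) {
  if (distant_max >= close_min) stop("distant_max must be < close_min")
  n <- nrow(K)
  labels <- rownames(K)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  idx <- which(upper.tri(K), arr.ind = TRUE)
  k <- K[upper.tri(K)]
  stratum <- ifelse(k <= distant_max, "distant",
                    ifelse(k >= close_min, "close", "intermediate"))
  data.frame(
    id_i = labels[idx[, 1]], id_j = labels[idx[, 2]],
    kinship = k, stratum = stratum,
    stringsAsFactors = FALSE
  )
}
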