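#' Principal components of the genomic relationship matrix
#'
#' Eigendecomposition of the GRM (equivalent to an SVD of the standardized
#' genotype matrix). Because the GRM is built from column-centered
#' genotypes, scores of non-null components have exactly zero mean. Sign
#' convention: within each component the largest-magnitude score is
#' positive.
#'
#' @param X genotype matrix (individuals x SNPs) or a precomputed genomic
#'   \code{relationship_matrix}.
#' @param n_components number of leading components to return.
#' @return matrix of scores, individuals x components (columns PC1..PCk).
#' @export
genotype_pca <- function(X, n_components = 5) {
  G <- if (inherits(X, "relationship_matrix")) X else compute_grm(X)
  eg <- eigen(G, symmetric = TRUE)
  pos <- sum(eg$values > 1e-8)
  if (n_components > pos) {
    stop("n_components (", n_components, ") exceeds GRM rank (", pos, ")")
  }
  scores <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(n_components)]), n_components)
  for (j in seq_len(ncol(scores))) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(n_components)))
  scores
}

# restricted log-likelihood profiled over the variance ratio, in
# eigen-rotated coordinates; returns the pieces reml_fit needs
.reml_profile <- function(ratio, d, ytil, Qtil, logdet_QtQ) {
  n <- length(ytil)
  c <- ncol(Qtil)
  v <- ratio * d + (1 - ratio)
  if (any(v <= 0)) return(list(ll = -Inf))
  w <- 1 / v
  WQ <- Qtil * w
  A <- crossprod(Qtil, WQ)
  b <- crossprod(WQ, ytil)
  beta <- solve(A, b)
  r <- ytil - Qtil %*% beta
  rss <- sum(w * r^2)
  sigma2 <- rss / (n - c)
  ll <- -0.5 * ((n - c) * log(2 * pi * sigma2) + (n - c) + sum(log(v)) +
                  determinant(A, logarithm = TRUE)$modulus - logdet_QtQ)
  list(ll = as.numeric(ll), sigma2 = sigma2, beta = beta)
}

#' REML fit of a single-random-component mixed model
#'
#' Model: y = Q alpha + u + e with u ~ N(0, K sigma2_random) and
#' e ~ N(0, I sigma2_residual). K is eigendecomposed once and the
#' restricted log-likelihood is profiled over the variance ratio
#' sigma2_random / (sigma2_random + sigma2_residual) on [0, 1] by bounded
#' one-dimensional optimization (tolerance 1e-8), the FaST-LMM strategy --
#' exact for one component and free of convergence tuning.
#'
#' @param y numeric trait vector.
#' @param Q covariate matrix including the intercept column (default
#'   intercept only).
#' @param K positive-semidefinite \code{relationship_matrix} (or plain
#'   symmetric matrix) conformable with y.
#' @return \code{varcomp_fit} list: \code{sigma2_random},
#'   \code{sigma2_residual}, \code{ratio} (h2 or m2), \code{loglik}
#'   (restricted), \code{se_ratio} (finite-difference curvature),
#'   \code{converged}, \code{boundary}, \code{n}, plus the eigen pieces
#'   reused by the association scan.
#' @export
reml_fit <- function(y, K, Q = NULL) {
  n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  Q <- as.matrix(Q)
  if (nrow(Q) != n || nrow(K) != n) stop("y, Q and K dimensions disagree")
  if (n <= ncol(Q) + 1) stop("too few observations for the covariate set")
  if (qr(Q)$rank < ncol(Q)) stop("covariate matrix Q is singular")
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6) {
    warning("K has eigenvalues below -1e-6; clipped to zero")
  }
  if (stats::sd(d) < 1e-8) {
    warning("K is (near) proportional to the identity; variance components unidentifiable")
  }
  U <- eg$vectors
  ytil <- as.vector(crossprod(U, y))
  Qtil <- crossprod(U, Q)
  logdet_QtQ <- as.numeric(determinant(crossprod(Q), logarithm = TRUE)$modulus)
  f <- function(h) .reml_profile(h, d, ytil, Qtil, logdet_QtQ)$ll
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  # optimize() never evaluates the endpoints; compare against them
  cand <- c(opt$maximum, 0, 1 - 1e-10)
  lls <- vapply(cand, f, 0)
  h <- cand[which.max(lls)]
  prof <- .reml_profile(h, d, ytil, Qtil, logdet_QtQ)
  boundary <- h < 1e-6 || h > 1 - 1e-6
  # curvature of the profile restricted likelihood at the optimum
  delta <- 1e-4
  h_lo <- max(h - delta, 0); h_hi <- min(h + delta, 1 - 1e-12)
  curv <- (f(h_hi) - 2 * prof$ll + f(h_lo)) / ((h_hi - h) * (h - h_lo) +
                                                 .Machine$double.eps)
  se <- if (!boundary && is.finite(curv) && curv < 0) sqrt(-1 / curv) else NA_real_
  structure(list(
    sigma2_random = h * prof$sigma2,
    sigma2_residual = (1 - h) * prof$sigma2,
    ratio = h,
    loglik = prof$ll,
    se_ratio = se,
    converged = TRUE,
    boundary = boundary,
    n = n,
    beta = as.vector(prof$beta),
    eigen_values = d,
    eigen_vectors = U
  ), class = "varcomp_fit")
}

#' Variance in a trait explained by genetics or a site's microbiota
#'
#' Dispatches to \code{\link{reml_fit}} with the genomic relationship
#' matrix (heritability, h2) or the microbial relationship matrix of one
#' sampling site (microbiability, m2). Covariates always include an
#' intercept and the top genetic principal components; for microbiability
#' the leading principal components of the trait-associated SNPs (when
#' supplied) are added, so the microbial component is estimated after
#' correcting for host genetics.
#'
#' @param bundle a \code{dataset_bundle} (see \code{\link{simulate_bundle}}
#'   or \code{\link{load_dataset}}).
#' @param component \code{"genomic"} or a site label present in
#'   \code{bundle$abundances}.
#' @param trait phenotype column name (default \code{"rfi"}).
#' @param n_gen_pcs number of genetic PCs in the covariate set (default 5).
#' @param trait_snps optional SNP ids previously associated with the trait;
#'   their first \code{n_snp_pcs} PCs join the covariates for site
#'   components.
#' @param n_snp_pcs number of trait-SNP PCs (default 3).
#' @return a \code{varcomp_fit} (see \code{\link{reml_fit}}) with the
#'   component label attached.
#' @export
variance_explained <- function(bundle, component, trait = "rfi",
                               n_gen_pcs = 5, trait_snps = NULL,
                               n_snp_pcs = 3) {
  phen <- bundle$phenotypes
  if (!trait %in% names(phen)) stop("trait column not found: ", trait)
  G <- compute_grm(bundle$genotypes)
  pcs <- genotype_pca(G, n_gen_pcs)
  if (identical(component, "genomic")) {
    ids <- rownames(bundle$genotypes)
    K <- G
    Q <- cbind(1, pcs)
  } else {
    if (!component %in% names(bundle$abundances)) {
      stop("unknown component/site: ", component)
    }
    A <- bundle$abundances[[component]]
    if (nrow(A) == 0) stop("site has no samples: ", component)
    ids <- rownames(A)
    if (!all(ids %in% rownames(bundle$genotypes))) {
      stop("site samples missing genotypes: ",
           paste(setdiff(ids, rownames(bundle$genotypes)), collapse = ", "))
    }
    K <- compute_mrm(A)
    Q <- cbind(1, pcs[ids, , drop = FALSE])
    if (!is.null(trait_snps) && length(trait_snps) > 0) {
      Xs <- bundle$genotypes[ids, intersect(trait_snps, colnames(bundle$genotypes)),
                             drop = FALSE]
      Xs <- Xs[, apply(Xs, 2, stats::sd) > 0, drop = FALSE]
      if (ncol(Xs) > 0) {
        k <- min(n_snp_pcs, ncol(Xs), nrow(Xs) - 1)
        sv <- svd(scale(Xs), nu = k, nv = 0)
        Q <- cbind(Q, sv$u[, seq_len(k), drop = FALSE] %*%
                     diag(sv$d[seq_len(k)], k))
      }
    }
  }
  y <- phen[[trait]][match(ids, phen$id)]
  if (anyNA(y)) stop("trait missing for some samples")
  fit <- reml_fit(y, K, Q)
  fit$component <- component
  fit
}
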