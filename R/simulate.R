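#' @title Synthetic study generator
#' @description Generates genotypes with family structure, zero-inflated
#'   log-normal compositional microbiota per sampling site (optionally
#'   shifted by host SNP genotype), and a phenotype with configurable
#'   additive-genetic and microbial variance fractions, so every pipeline
#'   stage can be validated against known ground truth.
#' @name synthetic-data
NULL

default_sites <- function() c("duodenum", "jejunum", "ileum", "cecum", "feces")

# one Mendelian gamete per SNP from an additive-coded parent genotype
.gamete <- function(geno) {
  het <- geno == 1L
  allele <- as.integer(geno == 2L)
  allele[het] <- stats::rbinom(sum(het), 1L, 0.5)
  allele
}

#' Simulate family-structured biallelic genotypes
#'
#' Founders are drawn from Hardy-Weinberg equilibrium with per-SNP allele
#' frequencies uniform over \code{maf_range}; each family has two distinct
#' founder parents whose full-sib offspring are produced by Mendelian
#' transmission. Genotypes are recoded to minor-allele counts; SNPs that
#' come out monomorphic are resampled.
#'
#' @param n_founders number of founder individuals (all retained).
#' @param n_families number of full-sib families.
#' @param sibs_per_family offspring per family.
#' @param M number of SNPs (must be >= 50).
#' @param maf_range length-2 vector within [0.05, 0.5] for founder allele
#'   frequencies.
#' @param seed integer seed.
#' @return list with \code{genotypes} (individuals x SNPs 0/1/2 matrix,
#'   rownames ids, colnames SNP ids), \code{snp_info} (id, chrom, pos,
#'   maf), and \code{pedigree} (id, sire, dam, family; NA parents for
#'   founders).
#' @export
simulate_genotypes <- function(n_founders, n_families = 0, sibs_per_family = 0,
                               M = 1000, maf_range = c(0.05, 0.5), seed = 1) {
  if (M < 50) stop("M < 50: relationship matrices too unstable to be useful")
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12) {
    stop("maf_range must lie within [0.05, 0.5]")
  }
  if (n_families > 0 && sibs_per_family < 2) {
    warning("sibs_per_family < 2: no close-relative pairs will exist")
  }
  if (n_families > 0 && n_founders < 2) stop("need >= 2 founders to form families")
  set.seed(seed)
  n_off <- n_families * sibs_per_family
  n <- n_founders + n_off
  p <- stats::runif(M, maf_range[1], maf_range[2])
  founders <- vapply(p, function(pp) stats::rbinom(n_founders, 2L, pp),
                     integer(n_founders))
  founders <- matrix(founders, nrow = n_founders)
  sire <- dam <- rep(NA_integer_, n)
  fam <- rep(NA_integer_, n)
  X <- matrix(0L, n, M)
  X[seq_len(n_founders), ] <- founders
  if (n_families > 0) {
    parents <- vapply(seq_len(n_families),
                      function(i) sample.int(n_founders, 2L), integer(2))
    row <- n_founders
    for (f in seq_len(n_families)) {
      pg <- X[parents[1, f], ]
      mg <- X[parents[2, f], ]
      for (s in seq_len(sibs_per_family)) {
        row <- row + 1
        X[row, ] <- .gamete(pg) + .gamete(mg)
        sire[row] <- parents[1, f]
        dam[row] <- parents[2, f]
        fam[row] <- f
      }
    }
  }
  # recode to minor allele, resample monomorphic SNPs from fresh frequencies
  for (iter in 1:20) {
    freq <- colMeans(X) / 2
    flip <- freq > 0.5
    X[, flip] <- 2L - X[, flip]
    freq[flip] <- 1 - freq[flip]
    mono <- freq == 0
    if (!any(mono)) break
    for (j in which(mono)) {
      pp <- stats::runif(1, maf_range[1], maf_range[2])
      col <- stats::rbinom(n_founders, 2L, pp)
      X[seq_len(n_founders), j] <- col
      if (n_off > 0) {
        for (f in seq_len(n_families)) {
          rows <- n_founders + (f - 1) * sibs_per_family + seq_len(sibs_per_family)
          pg <- X[parents[1, f], j]
          mg <- X[parents[2, f], j]
          X[rows, j] <- stats::rbinom(sibs_per_family, 1L, pg / 2) +
            stats::rbinom(sibs_per_family, 1L, mg / 2)
        }
      }
    }
  }
  ids <- sprintf("ind%04d", seq_len(n))
  snps <- sprintf("snp%05d", seq_len(M))
  dimnames(X) <- list(ids, snps)
  list(
    genotypes = X,
    snp_info = data.frame(
      id = snps,
      chrom = rep_len(paste0("chr", 1:5), M)[order(rep_len(1:5, M))],
      pos = seq_len(M) * 1000L,
      maf = colMeans(X) / 2,
      stringsAsFactors = FALSE
    ),
    pedigree = data.frame(
      id = ids,
      sire = ifelse(is.na(sire), NA_character_, ids[sire]),
      dam = ifelse(is.na(dam), NA_character_, ids[dam]),
      family = fam,
      stringsAsFactors = FALSE
    )
  )
}

#' Simulate a zero-inflated log-normal abundance table for one site
#'
#' Each taxon abundance is Bernoulli(presence) x exp(Normal(mu_taxon +
#' genotype x shift, sigma_taxon)); rows are renormalized to proportions.
#' A sample that would be entirely absent keeps its most prevalent taxon so
#' compositional closure is always possible.
#'
#' @param n number of samples.
#' @param q number of taxa (>= 2).
#' @param presence per-taxon presence probabilities in (0, 1], length q
#'   (recycled if scalar).
#' @param log_mean,log_sd per-taxon log-scale (natural log) location and
#'   scale, length q (recycled).
#' @param snp_links optional data.frame (snp, taxon, shift): per minor
#'   allele copy, shift added to the taxon's natural-log abundance.
#' @param genotypes genotype matrix (needed when \code{snp_links} given);
#'   its rownames become sample ids prefix.
#' @param taxa taxon labels (default genus-style lineage strings).
#' @param seed integer seed.
#' @return samples x taxa matrix of relative abundances (rows sum to 1).
#' @export
simulate_microbiota <- function(n, q, presence = 0.8, log_mean = 0, log_sd = 1,
                                snp_links = NULL, genotypes = NULL,
                                taxa = NULL, seed = 1) {
  if (q < 2) stop("need at least 2 taxa")
  presence <- rep_len(presence, q)
  if (any(presence <= 0 | presence > 1)) stop("presence probabilities must be in (0, 1]")
  log_mean <- rep_len(log_mean, q)
  log_sd <- rep_len(log_sd, q)
  if (any(!is.finite(log_mean)) || any(!is.finite(log_sd))) {
    stop("log-normal parameters must be finite")
  }
  if (is.null(taxa)) taxa <- sprintf("g__taxon%03d", seq_len(q))
  set.seed(seed)
  shift_mat <- matrix(0, n, q)
  if (!is.null(snp_links) && nrow(snp_links) > 0) {
    if (is.null(genotypes)) stop("genotypes required when snp_links are given")
    if (nrow(genotypes) != n) stop("genotypes must have one row per sample")
    for (i in seq_len(nrow(snp_links))) {
      if (!snp_links$snp[i] %in% colnames(genotypes)) {
        stop("snp_links references absent SNP: ", snp_links$snp[i])
      }
      j <- match(snp_links$taxon[i], taxa)
      if (is.na(j)) stop("snp_links references absent taxon: ", snp_links$taxon[i])
      shift_mat[, j] <- shift_mat[, j] +
        genotypes[, snp_links$snp[i]] * snp_links$shift[i]
    }
  }
  present <- matrix(stats::rbinom(n * q, 1L, rep(presence, each = n)), n, q)
  value <- exp(matrix(stats::rnorm(n * q, rep(log_mean, each = n),
                                   rep(log_sd, each = n)), n, q) + shift_mat)
  A <- present * value
  empty <- rowSums(A) == 0
  if (any(empty)) {
    j <- which.max(presence)
    A[empty, j] <- value[empty, j]
  }
  A <- A / rowSums(A)
  dimnames(A) <- list(if (!is.null(genotypes)) rownames(genotypes)
                      else sprintf("s%04d", seq_len(n)), taxa)
  A
}

#' Simulate a phenotype with configured genetic and microbial fractions
#'
#' Genetic value = sum over causal SNPs of standardized genotype x effect;
#' microbial value = sum over effect taxa of standardized log10 abundance x
#' effect. Components are rescaled so the realized variance fractions equal
#' \code{true_h2} and \code{true_m2}; residual noise fills the remainder to
#' unit total variance. Also emits ADFI/ADG/body-weight columns constructed
#' so that \code{\link{compute_rfi}} on them returns the simulated trait.
#'
#' @param genotypes individuals x SNPs matrix.
#' @param abundances samples x taxa matrix aligned with genotype rows
#'   (used for the microbial component; may be NULL when true_m2 = 0).
#' @param true_h2,true_m2 target variance fractions (sum <= 1).
#' @param n_causal_snps,n_causal_taxa numbers of causal predictors.
#' @param seed integer seed.
#' @return list with \code{phenotypes} (data.frame id, adfi, adg, bw_start,
#'   bw_end, mmw, rfi), \code{truth} (true_h2, true_m2, causal_snp_effects,
#'   taxon_effects, genetic_value, microbial_value, seed).
#' @export
simulate_phenotype <- function(genotypes, abundances = NULL,
                               true_h2 = 0.39, true_m2 = 0.28,
                               n_causal_snps = 100, n_causal_taxa = 10,
                               seed = 1) {
  if (true_h2 < 0 || true_m2 < 0 || true_h2 + true_m2 > 1) {
    stop("need true_h2 >= 0, true_m2 >= 0, true_h2 + true_m2 <= 1")
  }
  set.seed(seed)
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  rescale <- function(v, target) {
    if (target == 0 || stats::sd(v) == 0) return(rep(0, n))
    (v - mean(v)) / stats::sd(v) * sqrt(target)
  }
  snp_eff <- numeric(0)
  g <- rep(0, n)
  if (true_h2 > 0) {
    poly <- which(apply(genotypes, 2, stats::sd) > 0)
    causal <- sample(poly, min(n_causal_snps, length(poly)))
    snp_eff <- stats::rnorm(length(causal))
    names(snp_eff) <- colnames(genotypes)[causal]
    g <- scale(genotypes[, causal, drop = FALSE]) %*% snp_eff
    g <- rescale(as.vector(g), true_h2)
  }
  tax_eff <- numeric(0)
  m <- rep(0, n)
  if (true_m2 > 0) {
    if (is.null(abundances)) stop("abundances required when true_m2 > 0")
    L <- log10(abundances + abundance_pseudocount(abundances))
    varying <- which(apply(L, 2, stats::sd) > 0)
    causal_t <- sample(varying, min(n_causal_taxa, length(varying)))
    tax_eff <- stats::rnorm(length(causal_t))
    names(tax_eff) <- colnames(abundances)[causal_t]
    m <- scale(L[, causal_t, drop = FALSE]) %*% tax_eff
    m <- rescale(as.vector(m), true_m2)
  }
  e <- rescale(stats::rnorm(n), 1 - true_h2 - true_m2)
  y <- g + m + e
  # growth records whose OLS residual reproduces y (up to the projection
  # onto the ADG/MMW design, which is independent noise)
  adg <- stats::rnorm(n, 55, 5)
  bw_start <- stats::rnorm(n, 1500, 100)
  bw_end <- bw_start + adg * 20
  mmw <- metabolic_midweight(bw_start, bw_end)
  rfi <- stats::lm.fit(cbind(1, adg, mmw), y)$residuals
  adfi <- 10 + 2 * adg + 0.5 * mmw + rfi
  list(
    phenotypes = data.frame(
      id = ids, adfi = adfi, adg = adg, bw_start = bw_start,
      bw_end = bw_end, mmw = mmw, rfi = unname(rfi),
      stringsAsFactors = FALSE
    ),
    truth = list(
      true_h2 = true_h2, true_m2 = true_m2,
      causal_snp_effects = snp_eff, taxon_effects = tax_eff,
      genetic_value = g, microbial_value = m, seed = seed
    )
  )
}

#' Simulate a complete multi-site dataset bundle
#'
#' Convenience wrapper tying the three generators together: genotypes with
#' family structure, one abundance table per sampling site with
#' site-specific presence profiles, and a phenotype whose microbial
#' component is driven by the taxa of one chosen site.
#'
#' @param n_founders,n_families,sibs_per_family,M genotype design
#'   (see \code{\link{simulate_genotypes}}).
#' @param q taxa per site.
#' @param sites character vector of site labels.
#' @param true_h2,true_m2 phenotype variance fractions; the microbial
#'   component uses \code{m2_site}.
#' @param m2_site site whose taxa carry the microbial effect.
#' @param snp_links optional SNP-to-taxon shift specification applied to
#'   every site (see \code{\link{simulate_microbiota}}).
#' @param seed integer seed.
#' @return a \code{dataset_bundle}: list with \code{genotypes},
#'   \code{snp_info}, \code{pedigree}, \code{abundances} (named list of
#'   site matrices), \code{phenotypes}, \code{truth}, \code{sites}.
#' @export
simulate_bundle <- function(n_founders = 60, n_families = 25,
                            sibs_per_family = 6, M = 2000, q = 100,
                            sites = c("cecum", "feces"),
                            true_h2 = 0.39, true_m2 = 0.28,
                            m2_site = sites[1], snp_links = NULL, seed = 1) {
  if (!m2_site %in% sites) stop("m2_site must be one of sites")
  set.seed(seed)
  geno <- simulate_genotypes(n_founders, n_families, sibs_per_family, M,
                             seed = seed)
  n <- nrow(geno$genotypes)
  abund <- list()
  for (i in seq_along(sites)) {
    presence <- stats::rbeta(q, 4, 1.2)          # mostly common, some rare
    presence <- pmin(pmax(presence, 0.05), 1)
    abund[[sites[i]]] <- simulate_microbiota(
      n, q,
      presence = presence,
      log_mean = stats::rnorm(q, 0, 1.5), log_sd = stats::runif(q, 0.5, 1.5),
      snp_links = snp_links, genotypes = geno$genotypes,
      seed = seed + 1000 * i
    )
  }
  ph <- simulate_phenotype(geno$genotypes, abund[[m2_site]],
                           true_h2 = true_h2, true_m2 = true_m2,
                           seed = seed + 77)
  ph$truth$m2_site <- m2_site
  structure(list(
    genotypes = geno$genotypes, snp_info = geno$snp_info,
    pedigree = geno$pedigree, abundances = abund,
    phenotypes = ph$phenotypes, truth = ph$truth, sites = sites,
    seed = seed
  ), class = "dataset_bundle")
}
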