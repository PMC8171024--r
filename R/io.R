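#' @title Readers, writers and the pipeline driver
#' @description Tab-delimited and VCF input, validated dataset bundles,
#'   deterministic table output, and the end-to-end driver that runs every
#'   analysis stage in order.
#' @name io
NULL

#' Pipeline configuration
#'
#' Validates thresholds and collects paths/options for
#' \code{\link{run_pipeline}}. All probability-like thresholds must lie in
#' [0, 1], the extreme-group size k must be >= 2, and resampling reps >= 1.
#'
#' @param sites sampling-site labels in use.
#' @param maf_min minimum minor allele frequency.
#' @param prevalence_min two-part model detection-rate cutoff.
#' @param network_prevalence_min co-occurrence network detection cutoff.
#' @param r_cut,p_cut network correlation and adjusted-p cutoffs.
#' @param distant_max,close_min kinship strata bounds.
#' @param resample_pairs pairs per stratum per replicate.
#' @param resample_reps number of resampling replicates.
#' @param k extreme-group size.
#' @param seed integer random seed, recorded in all outputs.
#' @param out_dir output directory.
#' @param paths named list of input paths (genotypes, snp_info, phenotypes,
#'   abundances = named list site -> path, id_map), or NULL for synthetic
#'   mode.
#' @param synthetic named list of arguments to
#'   \code{\link{simulate_bundle}}, used when \code{paths} is NULL.
#' @return a validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(sites = c("cecum", "feces"),
                            maf_min = 0.05, prevalence_min = 0.30,
                            network_prevalence_min = 0.95,
                            r_cut = 0.3, p_cut = 0.05,
                            distant_max = 0.05, close_min = 0.10,
                            resample_pairs = 100, resample_reps = 200,
                            k = 10, seed = 1, out_dir = tempfile("microFE_"),
                            paths = NULL, synthetic = list()) {
  probs <- c(maf_min = maf_min, prevalence_min = prevalence_min,
             network_prevalence_min = network_prevalence_min,
             p_cut = p_cut, distant_max = distant_max, close_min = close_min)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("thresholds outside [0, 1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (k < 2) stop("extreme-group size k must be >= 2")
  if (resample_reps < 1) stop("resample_reps must be >= 1")
  if (distant_max >= close_min) stop("distant_max must be < close_min")
  structure(list(
    sites = sites, maf_min = maf_min, prevalence_min = prevalence_min,
    network_prevalence_min = network_prevalence_min, r_cut = r_cut,
    p_cut = p_cut, distant_max = distant_max, close_min = close_min,
    resample_pairs = resample_pairs, resample_reps = resample_reps,
    k = k, seed = as.integer(seed), out_dir = out_dir, paths = paths,
    synthetic = synthetic
  ), class = "pipeline_config")
}

#' Write records as a deterministic tab-delimited table
#'
#' Stable column order (as given), floats at fixed precision, rows sorted
#' by the key columns; writing the same records twice yields byte-identical
#' files. An empty record set produces a header-only file.
#'
#' @param records data.frame.
#' @param path output path.
#' @param key column names to sort rows by (default: first column).
#' @param digits significant digits for numeric columns (default 8).
#' @return invisibly, the path.
#' @export
write_table <- function(records, path, key = names(records)[1], digits = 8) {
  stopifnot(is.data.frame(records))
  if (nrow(records) > 0 && length(key) > 0) {
    records <- records[do.call(order, records[, key, drop = FALSE]), ,
                       drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = digits, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write table to ", path)
  invisible(path)
}

#' Write / read a genotype matrix as TSV with a SNP metadata sidecar
#'
#' Rows are individuals (first column \code{id}), remaining columns one
#' per SNP with 0/1/2 minor-allele counts; the sidecar carries columns
#' id, chrom, pos, ref, alt.
#'
#' @param X genotype matrix with dimnames.
#' @param snp_info SNP metadata data.frame (id first).
#' @param path,info_path output paths.
#' @return invisibly, \code{path}.
#' @export
write_genotypes <- function(X, path, snp_info = NULL,
                            info_path = paste0(path, ".snps")) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(snp_info)) {
    utils::write.table(snp_info, info_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotype_matrix <- function(path, info_path = paste0(path, ".snps")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("malformed genotype header: first column must be 'id'")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$id
  info <- if (file.exists(info_path)) {
    utils::read.delim(info_path, stringsAsFactors = FALSE)
  } else NULL
  list(genotypes = X, snp_info = info)
}

#' Read biallelic genotypes from a VCF file
#'
#' Non-biallelic records are skipped (count logged); genotypes are recoded
#' to minor-allele counts per SNP; missing calls become NA.
#'
#' @param path VCF path (plain or gzipped).
#' @return list with \code{genotypes} (individuals x SNPs, NAs for
#'   missing) and \code{snp_info} (id, chrom, pos, ref, alt).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$ALT) > 0
  if (any(!biallelic)) {
    message("skipping ", sum(!biallelic), " non-biallelic VCF record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    ifelse(is.na(g) | g %in% c("./.", "."), NA_real_,
           ifelse(g == "0/0", 0, ifelse(g %in% c("0/1", "1/0"), 1,
                                        ifelse(g == "1/1", 2, NA_real_))))
  }
  X <- t(apply(gt, 2, count_alt))
  if (is.null(dim(X))) X <- matrix(X, nrow = ncol(gt))
  colnames(X) <- ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(X) <- colnames(gt)
  # orient to minor-allele counts
  freq <- colMeans(X, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  X[, flip] <- 2 - X[, flip]
  list(
    genotypes = X,
    snp_info = data.frame(id = colnames(X), chrom = fix$CHROM,
                          pos = as.integer(fix$POS), ref = fix$REF,
                          alt = fix$ALT, stringsAsFactors = FALSE)
  )
}

#' Mean-impute missing genotypes per SNP
#'
#' @param X genotype matrix with NAs.
#' @return matrix without NAs (SNP means substituted).
#' @export
impute_genotypes <- function(X) {
  if (!anyNA(X)) return(X)
  for (j in which(colSums(is.na(X)) > 0)) {
    m <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- if (is.finite(m)) m else 0
  }
  X
}

#' Write / read an abundance table (samples x taxa TSV)
#'
#' On read, rows are renormalized to proportions when all row sums agree
#' to a common constant within relative 1e-6 (so percentage tables are
#' accepted); inconsistent row sums are an error.
#'
#' @param A abundance matrix with dimnames.
#' @param path file path.
#' @return \code{read_abundance_table}: samples x taxa matrix of
#'   proportions.
#' @export
write_abundance_table <- function(A, path) {
  df <- data.frame(sample_id = rownames(A), A, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("malformed abundance header: first column must be 'sample_id'")
  }
  A <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(A) <- "double"
  rownames(A) <- df$sample_id
  rs <- rowSums(A)
  if (any(rs <= 0)) stop("sample(s) with non-positive total abundance")
  if (max(abs(rs - stats::median(rs))) / stats::median(rs) > 1e-6) {
    stop("row sums are not a common constant; cannot renormalize safely")
  }
  A / rs
}

#' Write / read a phenotype table (CSV)
#'
#' Columns: id, adfi, adg, bw_start, bw_end, optionally mmw and rfi.
#'
#' @param phen phenotype data.frame.
#' @param path file path.
#' @return \code{read_phenotypes}: the data.frame.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.csv(phen, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "adfi", "adg")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df
}

#' Assemble and validate a dataset bundle from files
#'
#' @param config a \code{\link{pipeline_config}} whose \code{paths} list
#'   names the genotype file (TSV or VCF, by extension), the phenotype CSV
#'   and one abundance TSV per site; an optional \code{id_map} TSV
#'   (sample_id, individual_id, site) maps microbiome samples to
#'   individuals, defaulting to identity.
#' @return a validated \code{dataset_bundle}.
#' @export
load_dataset <- function(config) {
  paths <- config$paths
  if (is.null(paths)) stop("config carries no input paths")
  for (p in c(paths$genotypes, paths$phenotypes, unlist(paths$abundances))) {
    if (!file.exists(p)) stop("input file missing: ", p)
  }
  geno <- if (grepl("\\.vcf(\\.gz)?$", paths$genotypes)) {
    read_genotypes_vcf(paths$genotypes)
  } else {
    read_genotype_matrix(paths$genotypes)
  }
  X <- impute_genotypes(geno$genotypes)
  phen <- read_phenotypes(paths$phenotypes)
  site_labels <- names(paths$abundances)
  unknown <- setdiff(site_labels, config$sites)
  if (length(unknown) > 0) {
    stop("unknown site label(s): ", paste(unknown, collapse = ", "))
  }
  id_map <- if (!is.null(paths$id_map)) {
    utils::read.delim(paths$id_map, stringsAsFactors = FALSE)
  } else NULL
  abund <- list()
  for (s in site_labels) {
    A <- read_abundance_table(paths$abundances[[s]])
    if (!is.null(id_map)) {
      m <- id_map[id_map$site == s, , drop = FALSE]
      ind <- m$individual_id[match(rownames(A), m$sample_id)]
      if (anyNA(ind)) {
        stop("samples without individual mapping in site ", s, ": ",
             paste(rownames(A)[is.na(ind)], collapse = ", "))
      }
      rownames(A) <- ind
    }
    orphans <- setdiff(rownames(A), rownames(X))
    if (length(orphans) > 0) {
      stop("site ", s, " samples with no genotyped individual: ",
           paste(orphans, collapse = ", "))
    }
    abund[[s]] <- A
  }
  if (anyDuplicated(rownames(X))) stop("duplicate individual ids in genotypes")
  orphans <- setdiff(rownames(X), phen$id)
  if (length(orphans) > 0) {
    stop("individuals without phenotype records: ",
         paste(orphans, collapse = ", "))
  }
  structure(list(
    genotypes = X, snp_info = geno$snp_info, pedigree = NULL,
    abundances = abund, phenotypes = phen, truth = NULL,
    sites = config$sites, seed = config$seed
  ), class = "dataset_bundle")
}

#' Write every table of a dataset bundle to a directory
#'
#' @param bundle a \code{dataset_bundle}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.tsv"),
                  bundle$snp_info)
  for (s in names(bundle$abundances)) {
    write_abundance_table(bundle$abundances[[s]],
                          file.path(dir, paste0("abundance_", s, ".tsv")))
  }
  write_phenotypes(bundle$phenotypes, file.path(dir, "phenotypes.csv"))
  if (!is.null(bundle$truth)) {
    truth <- bundle$truth
    truth$genetic_value <- NULL
    truth$microbial_value <- NULL
    # keep predictor names: named atomic vectors lose names in JSON arrays
    truth$causal_snp_effects <- as.list(truth$causal_snp_effects)
    truth$taxon_effects <- as.list(truth$taxon_effects)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: RFI computation, relationship matrices (GRM, per-site
#' MRM and Bray-Curtis), kinship-stratified similarity resampling per
#' site, variance components (h2 and per-site m2), GWAS on the trait,
#' two-part taxon screen with extreme-group tests, and per-site
#' co-occurrence networks. All outputs are written under
#' \code{config$out_dir} with the seed and configuration echoed as JSON;
#' the same seed and configuration reproduce identical files.
#'
#' @param config a \code{\link{pipeline_config}}. When \code{config$paths}
#'   is NULL a synthetic bundle is generated from \code{config$synthetic}.
#' @return invisibly, a list with the bundle and the per-stage results.
#' @export
run_pipeline <- function(config) {
  stage <- "setup"
  result <- tryCatch({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    bundle <- if (is.null(config$paths)) {
      stage <- "simulate"
      do.call(simulate_bundle, utils::modifyList(
        list(sites = config$sites, seed = config$seed), config$synthetic))
    } else {
      stage <- "load"
      load_dataset(config)
    }
    cfg_echo <- unclass(config)
    cfg_echo$paths <- lapply(cfg_echo$paths, unlist)
    jsonlite::write_json(cfg_echo, file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

    stage <- "rfi"
    phen <- bundle$phenotypes
    if (!"rfi" %in% names(phen)) phen <- compute_rfi(phen)
    bundle$phenotypes <- phen
    write_phenotypes(phen, file.path(config$out_dir, "phenotypes_rfi.csv"))

    stage <- "matrices"
    G <- compute_grm(bundle$genotypes)
    mrm <- lapply(bundle$abundances, compute_mrm)
    bc <- lapply(bundle$abundances, bray_curtis_matrix)

    stage <- "resampling"
    strata <- classify_relative_pairs(G, config$distant_max, config$close_min)
    resamp <- list()
    for (s in names(bc)) {
      resamp[[s]] <- kinship_similarity_resampling(
        G, bc[[s]], strata,
        n_distant = config$resample_pairs, n_close = config$resample_pairs,
        reps = config$resample_reps, seed = config$seed)
    }
    write_table(data.frame(
      site = names(resamp),
      mean_r = vapply(resamp, `[[`, 0, "mean"),
      ci_low = vapply(resamp, `[[`, 0, "ci_low"),
      ci_high = vapply(resamp, `[[`, 0, "ci_high"),
      seed = config$seed, stringsAsFactors = FALSE
    ), file.path(config$out_dir, "resampling.tsv"), key = "site")

    stage <- "varcomp"
    h2 <- variance_explained(bundle, "genomic")
    m2 <- lapply(names(bundle$abundances), function(s)
      variance_explained(bundle, s))
    names(m2) <- names(bundle$abundances)
    write_table(data.frame(
      component = c("genomic", names(m2)),
      ratio = c(h2$ratio, vapply(m2, `[[`, 0, "ratio")),
      sigma2_random = c(h2$sigma2_random, vapply(m2, `[[`, 0, "sigma2_random")),
      sigma2_residual = c(h2$sigma2_residual,
                          vapply(m2, `[[`, 0, "sigma2_residual")),
      loglik = c(h2$loglik, vapply(m2, `[[`, 0, "loglik")),
      boundary = c(h2$boundary, vapply(m2, `[[`, TRUE, "boundary")),
      stringsAsFactors = FALSE
    ), file.path(config$out_dir, "variance_components.tsv"), key = "component")

    stage <- "gwas"
    y <- phen$rfi[match(rownames(bundle$genotypes), phen$id)]
    pcs <- genotype_pca(G, min(5, nrow(G) - 2))
    M_eff <- effective_tests(bundle$genotypes, block_size = 500)
    gwas <- lmm_gwas(y, bundle$genotypes, G, Q = cbind(1, pcs),
                     sig_threshold = bonferroni_threshold(0.05, ncol(bundle$genotypes)),
                     sugg_threshold = bonferroni_threshold(0.05, M_eff))
    write_table(gwas, file.path(config$out_dir, "gwas_rfi.tsv"), key = "snp")

    stage <- "two_part"
    for (s in names(bundle$abundances)) {
      A <- bundle$abundances[[s]]
      ys <- phen$rfi[match(rownames(A), phen$id)]
      tp <- two_part_association(ys, A, config$prevalence_min, config$p_cut)
      k_use <- min(config$k, floor(nrow(A) / 2))
      eg <- extreme_group_screen(ys, A, k = k_use, p_cut = config$p_cut)
      merged <- merge(tp, eg, by = "taxon", all.x = TRUE)
      merged$sig_all <- merged$sig_both &
        (merged$sig_binary | merged$sig_quant)
      write_table(merged, file.path(config$out_dir,
                                    paste0("twopart_", s, ".tsv")),
                  key = "taxon")
    }

    stage <- "network"
    for (s in names(bundle$abundances)) {
      A <- tryCatch(
        prevalence_filter(bundle$abundances[[s]],
                          min_prevalence = config$network_prevalence_min),
        error = function(e) NULL)
      if (is.null(A) || ncol(A) < 3) next
      net <- cooccurrence_network(A, config$r_cut, config$p_cut)
      write_table(net, file.path(config$out_dir, paste0("network_", s, ".tsv")),
                  key = c("taxon_a", "taxon_b"))
    }
    list(bundle = bundle, h2 = h2, m2 = m2, gwas = gwas, resampling = resamp)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
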