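#' Stratified kinship vs microbial-similarity resampling
#'
#' Repeatedly draws pairs of individuals without replacement within kinship
#' strata (distant and close relatives), computes the Pearson correlation
#' between pair kinship and pair Bray-Curtis similarity over the drawn
#' pairs, and summarizes the replicate correlations by their mean and a
#' trimmed 95\% interval formed by discarding the lowest and highest 2.5\%
#' of replicate values and taking the extremes of the remainder.
#'
#' @param K genomic \code{relationship_matrix}.
#' @param S \code{relationship_matrix} of Bray-Curtis similarities with
#'   labels matching (a subset of) K's.
#' @param strata pair classification from
#'   \code{\link{classify_relative_pairs}}; only pairs whose both members
#'   carry similarities are usable.
#' @param n_distant,n_close pairs drawn per replicate from each stratum
#'   (defaults 500/500).
#' @param reps number of replicates (default 10000).
#' @param mode \code{"combined"} pools the two strata in one correlation;
#'   \code{"distant_only"} / \code{"close_only"} use a single stratum.
#' @param seed integer seed.
#' @return list: \code{correlations} (length-\code{reps} vector),
#'   \code{mean}, \code{ci_low}, \code{ci_high}, \code{n_distant_pool},
#'   \code{n_close_pool}, \code{mode}, \code{seed}.
#' @export
kinship_similarity_resampling <- function(K, S, strata,
                                          n_distant = 500, n_close = 500,
                                          reps = 10000,
                                          mode = c("combined", "distant_only",
                                                   "close_only"),
                                          seed = 1) {
  mode <- match.arg(mode)
  if (reps < 1) stop("reps must be >= 1")
  labs <- rownames(S)
  usable <- strata[strata$id_i %in% labs & strata$id_j %in% labs, , drop = FALSE]
  sim <- S[cbind(match(usable$id_i, labs), match(usable$id_j, labs))]
  kin <- usable$kinship
  di <- which(usable$stratum == "distant")
  cl <- which(usable$stratum == "close")
  need_d <- mode %in% c("combined", "distant_only")
  need_c <- mode %in% c("combined", "close_only")
  if (need_d && length(di) < n_distant) {
    stop("distant stratum has ", length(di), " pairs, need ", n_distant)
  }
  if (need_c && length(cl) < n_close) {
    stop("close stratum has ", length(cl), " pairs, need ", n_close)
  }
  set.seed(seed)
  cors <- vapply(seq_len(reps), function(r) {
    idx <- c(if (need_d) sample(di, n_distant) else integer(0),
             if (need_c) sample(cl, n_close) else integer(0))
    stats::cor(kin[idx], sim[idx])
  }, 0)
  drop_n <- floor(0.025 * reps)
  srt <- sort(cors)
  kept <- if (drop_n > 0) srt[(drop_n + 1):(reps - drop_n)] else srt
  list(
    correlations = cors,
    mean = mean(cors),
    ci_low = min(kept),
    ci_high = max(kept),
    n_distant_pool = length(di),
    n_close_pool = length(cl),
    mode = mode,
    seed = seed
  )
}
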