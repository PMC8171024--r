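#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Step-up false discovery rate adjustment. Values are validated to lie in
#' [0, 1] and returned in the original input order; \code{NA}s propagate.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("p-values outside [0, 1]: ", paste(utils::head(p[bad], 5), collapse = ", "))
  }
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum (Mann-Whitney) test between two samples
#'
#' Exact two-sided p-value by enumeration when the combined sample size is at
#' most \code{exact_max_n} and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max_n combined-size cutoff below which the exact distribution
#'   is used (default 20).
#' @return a \code{test_result} list: \code{statistic} (rank-sum W of the
#'   first sample, Mann-Whitney form), \code{p_raw}, \code{method},
#'   \code{n_a}, \code{n_b}, \code{exact}.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max_n = 20) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= exact_max_n && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b,
    exact = use_exact, correct = TRUE, alternative = "two.sided"
  ))
  structure(list(
    statistic = unname(wt$statistic),
    p_raw = min(1, wt$p.value),
    method = "wilcoxon_rank_sum",
    n_a = length(a), n_b = length(b),
    exact = use_exact
  ), class = "test_result")
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups named (or unnamed) list of numeric vectors, one per group;
#'   each group needs at least 2 observations.
#' @return list with \code{f}, \code{df_between}, \code{df_within},
#'   \code{p_raw}, and a data.frame \code{tukey} of pairwise comparisons
#'   (\code{group_a}, \code{group_b}, \code{diff}, \code{p_adj}).
#' @export
one_way_anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (stats::var(y) == 0) stop("no variance in the data")
  fit <- stats::aov(y ~ g)
  av <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(list(
    f = av[["F value"]][1],
    df_between = av[["Df"]][1],
    df_within = av[["Df"]][2],
    p_raw = av[["Pr(>F)"]][1],
    method = "one_way_anova",
    group_sizes = vapply(groups, length, 1L),
    tukey = data.frame(
      group_a = vapply(pairs, `[`, "", 2),
      group_b = vapply(pairs, `[`, "", 1),
      diff = unname(tk[, "diff"]),
      p_adj = unname(tk[, "p adj"]),
      stringsAsFactors = FALSE
    )
  ), class = "test_result")
}
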