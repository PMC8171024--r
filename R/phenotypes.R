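#' Metabolic mid-weight
#'
#' Mid-test average body weight raised to the 3/4 power, the standard
#' metabolic exponent; proxies maintenance requirements.
#'
#' @param bw_start,bw_end body weights (g) at test start and end.
#' @return numeric vector of metabolic mid-weights (g^0.75).
#' @export
metabolic_midweight <- function(bw_start, bw_end) {
  if (any(bw_start < 0 | bw_end < 0)) stop("body weights must be non-negative")
  ((bw_start + bw_end) / 2)^0.75
}

#' Residual feed intake
#'
#' RFI is the residual of average daily feed intake (ADFI) regressed by
#' ordinary least squares on average daily gain (ADG) and metabolic
#' mid-weight (MMW), with an intercept. Negative RFI means the bird ate less
#' than predicted from its growth and maintenance, i.e. was more efficient.
#'
#' @param phen data.frame with columns \code{id}, \code{adfi}, \code{adg},
#'   and either \code{mmw} or both \code{bw_start} and \code{bw_end}.
#' @return the input data.frame with columns \code{mmw} and \code{rfi}
#'   added, rows in input order.
#' @export
compute_rfi <- function(phen) {
  need <- c("id", "adfi", "adg")
  if (!all(need %in% names(phen))) {
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"mmw" %in% names(phen)) {
    if (!all(c("bw_start", "bw_end") %in% names(phen))) {
      stop("need mmw or bw_start/bw_end columns")
    }
    phen$mmw <- metabolic_midweight(phen$bw_start, phen$bw_end)
  }
  if (nrow(phen) < 4) stop("need at least 4 records to fit ADFI ~ ADG + MMW")
  if (anyNA(phen[, c("adfi", "adg", "mmw")])) stop("missing values in ADFI/ADG/MMW")
  X <- cbind(1, phen$adg, phen$mmw)
  if (kappa(crossprod(X)) > 1e12) stop("ADG and MMW are collinear; RFI not identifiable")
  fit <- stats::lm.fit(X, phen$adfi)
  phen$rfi <- unname(fit$residuals)
  phen
}
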