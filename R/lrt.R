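#' Branch-site likelihood-ratio statistic
#'
#' `2 * (lnL_alt - lnL_null)` for a branch-site test of positive selection.
#' The codon-model maximum-likelihood fits themselves are external; this
#' layer consumes their log-likelihood pairs. Negative statistics (numerical
#' optimizer noise in the external fits) are allowed and should be clamped
#' by [mixture_pvalue()].
#'
#' @param lnl_alt log-likelihood of the alternative model (omega2 free).
#' @param lnl_null log-likelihood of the null model (omega2 = 1 fixed).
#' @return the LRT statistic (vectorized).
#' @export
lrt_stat <- function(lnl_alt, lnl_null) {
  if (any(!is.finite(lnl_alt)) || any(!is.finite(lnl_null)))
    stop("log-likelihoods must be finite")
  2 * (lnl_alt - lnl_null)
}

#' Mixture p-value (p/2) for the branch-site LRT
#'
#' Under the null the statistic follows a 50:50 mixture of a point mass at 0
#' and a chi-square with 1 df, so the p-value is half the chi-square(1)
#' upper tail at `max(stat, 0)`. Always in `[0, 0.5]`.
#'
#' @param stat LRT statistic (vectorized; negatives are clamped to 0).
#' @return p/2 values.
#' @export
mixture_pvalue <- function(stat) {
  if (any(!is.finite(stat))) stop("statistic must be finite")
  0.5 * stats::pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` for a family of `m` tests.
#'
#' @param p p-values in `[0, 1]`.
#' @param m family size; must be at least `length(p)` (default: exactly that).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= number of p-values")
  pmin(1, p * m)
}

#' Branch-site LRT decision table
#'
#' Reads (or takes) a table of per-gene log-likelihood pairs for one or more
#' foreground branches and appends the LRT statistic, the mixture p/2, the
#' Bonferroni-adjusted p (family = genes tested on the same branch, unless
#' `m` overrides it) and a significance call.
#'
#' @param x data.frame with columns `gene`, `branch`, `lnl_alt`, `lnl_null`,
#'   or a path to such a TSV.
#' @param m Bonferroni family size; default is the per-branch gene count.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame with `lrt_stat`, `p_half`, `p_adjusted`, `significant`.
#' @export
run_lrt <- function(x, m = NULL, alpha = 0.05) {
  if (is.character(x))
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "branch", "lnl_alt", "lnl_null") %in% names(x)))
  x$lrt_stat <- lrt_stat(x$lnl_alt, x$lnl_null)
  x$p_half <- mixture_pvalue(x$lrt_stat)
  fam <- if (is.null(m)) ave(x$p_half, x$branch, FUN = length) else m
  x$p_adjusted <- bonferroni_vec(x$p_half, fam)
  x$significant <- x$p_adjusted < alpha
  x
}

bonferroni_vec <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}
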