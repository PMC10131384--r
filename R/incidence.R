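#' Two-proportion Z test for incidence comparison
#'
#' Pooled-proportion Z statistic for comparing case rates between two
#' populations: the numerator is the difference in proportions and the
#' denominator `sqrt(phat (1 - phat) (1/n1 + 1/n2))` with
#' `phat = (c1 + c2) / (n1 + n2)`. The printed form of the statistic takes
#' the absolute difference; the signed version (positive when population 1
#' has the higher rate) is retained alongside it. The two-sided p-value
#' comes from the standard normal.
#'
#' @param c1,c2 case counts.
#' @param n1,n2 person counts.
#' @return list with `z` (signed), `z_abs`, `p` (two-sided) and the pooled
#'   proportion `phat`.
#' @export
z_statistic <- function(c1, n1, c2, n2) {
  stopifnot(n1 > 0, n2 > 0, c1 >= 0, c2 >= 0, c1 <= n1, c2 <= n2)
  phat <- (c1 + c2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    stop("pooled proportion is 0 or 1: Z statistic undefined")
  z <- (c1 / n1 - c2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, z_abs = abs(z), p = 2 * stats::pnorm(-abs(z)), phat = phat)
}

#' Read an incidence record table
#'
#' TSV with columns `population`, `sex`, `cases`, `persons`. A `rate` column
#' (cases per 100,000) is derived for reporting.
#'
#' @param path TSV path.
#' @return data.frame of incidence records.
#' @export
read_incidence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("population", "sex", "cases", "persons") %in% names(df)))
  if (any(df$cases < 0 | df$cases > df$persons))
    stop("case counts must satisfy 0 <= cases <= persons")
  df$rate <- 1e5 * df$cases / df$persons
  df
}

#' All pairwise incidence Z tests, per sex
#'
#' Computes the Z statistic and two-sided p for every unordered population
#' pair within each sex, and lays them out as a matrix with Z above and p
#' below the diagonal.
#'
#' @param records data.frame as from [read_incidence()].
#' @return list per sex, each with `pairs` (tidy data.frame: pop1, pop2,
#'   z signed with pop1 as population 1, z_abs, p) and `matrix` (Z upper
#'   triangle, p lower triangle, NA diagonal).
#' @export
compare_all <- function(records) {
  stopifnot(all(c("population", "sex", "cases", "persons") %in% names(records)))
  out <- list()
  for (sx in unique(records$sex)) {
    d <- records[records$sex == sx, , drop = FALSE]
    if (anyDuplicated(d$population))
      stop("duplicate population labels within sex ", sx)
    if (nrow(d) < 2) stop("need at least 2 records per sex")
    pops <- d$population
    k <- length(pops)
    M <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    pairs <- list()
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      zt <- z_statistic(d$cases[i], d$persons[i], d$cases[j], d$persons[j])
      M[i, j] <- zt$z_abs
      M[j, i] <- zt$p
      pairs[[length(pairs) + 1L]] <- data.frame(
        pop1 = pops[i], pop2 = pops[j], z = zt$z, z_abs = zt$z_abs,
        p = zt$p, stringsAsFactors = FALSE)
    }
    out[[sx]] <- list(pairs = do.call(rbind, pairs), matrix = M)
  }
  out
}
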