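#' Sliding-window counts of large standardized scores
#'
#' SNPs with large absolute haplotype scores cluster under a sweep, so the
#' scan counts, in sliding windows of `window_size` consecutive scored SNPs
#' (step 1, per chromosome), how many exceed `|score| > score_cutoff`. A
#' chromosome with fewer scored SNPs than `window_size` yields a single
#' truncated window, flagged as such.
#'
#' @param track standardized `score_track`.
#' @param window_size number of scored SNPs per window (odd, default 51).
#' @param score_cutoff absolute standardized-score threshold (default 2).
#' @return data.frame of windows: `chrom`, `first`, `last` (indices into the
#'   scored SNPs of that chromosome), `start_pos`, `end_pos`, `span`,
#'   `count`, `truncated`. The scored-SNP row indices of the track are
#'   attached as attribute `"scored_rows"` (a list per chromosome).
#' @export
window_counts <- function(track, window_size = 51, score_cutoff = 2) {
  if (window_size %% 2 != 1) stop("window_size must be odd")
  scored <- !is.na(track$standardized)
  out <- list()
  scored_rows <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch & scored)
    scored_rows[[ch]] <- rows
    ns <- length(rows)
    if (ns == 0) next
    exceed <- abs(track$standardized[rows]) > score_cutoff
    if (ns < window_size) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, first = 1L, last = ns,
        start_pos = track$pos[rows[1]], end_pos = track$pos[rows[ns]],
        span = track$pos[rows[ns]] - track$pos[rows[1]],
        count = sum(exceed), truncated = TRUE, stringsAsFactors = FALSE)
      next
    }
    cs <- cumsum(c(0L, as.integer(exceed)))
    first <- seq_len(ns - window_size + 1L)
    last <- first + window_size - 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, first = first, last = last,
      start_pos = track$pos[rows[first]], end_pos = track$pos[rows[last]],
      span = track$pos[rows[last]] - track$pos[rows[first]],
      count = cs[last + 1L] - cs[first], truncated = FALSE,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), first = integer(0), last = integer(0),
               start_pos = integer(0), end_pos = integer(0), span = integer(0),
               count = integer(0), truncated = logical(0))
  attr(res, "scored_rows") <- scored_rows
  attr(res, "window_size") <- window_size
  attr(res, "score_cutoff") <- score_cutoff
  res
}

#' Top-quantile qualifying windows
#'
#' Pools the window exceedance counts (genome-wide, per statistic and
#' population pair) and qualifies a window iff its count is strictly greater
#' than the empirical `(1 - quantile)` percentile.
#'
#' @param windows data.frame from [window_counts()].
#' @param quantile upper-tail mass (default 0.01, i.e. top 1%).
#' @return the windows with a `qualify` column; the count threshold is
#'   attached as attribute `"threshold"`.
#' @export
top_window_flags <- function(windows, quantile = 0.01) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (nrow(windows) == 0) {
    windows$qualify <- logical(0)
    attr(windows, "threshold") <- NA_real_
    return(windows)
  }
  th <- as.numeric(stats::quantile(windows$count, probs = 1 - quantile,
                                   names = FALSE, type = 1))
  windows$qualify <- windows$count > th
  if (!any(windows$qualify) && length(unique(windows$count)) == 1)
    warning("degenerate window-count distribution: no window qualifies")
  attr(windows, "threshold") <- th
  windows
}

#' Per-SNP haplotype-test hits
#'
#' A SNP is a hit iff `|standardized score| > score_cutoff` and it lies
#' inside at least one qualifying window of its own track.
#'
#' @param track the standardized `score_track` the windows came from.
#' @param windows output of [top_window_flags()] for that track.
#' @param score_cutoff absolute-score threshold (default 2).
#' @return logical vector, one flag per track row.
#' @export
haplotype_hits <- function(track, windows, score_cutoff = 2) {
  hits <- rep(FALSE, nrow(track))
  if (!"qualify" %in% names(windows))
    stop("windows must come from top_window_flags()")
  scored_rows <- attr(windows, "scored_rows")
  exceed <- !is.na(track$standardized) &
    abs(track$standardized) > score_cutoff
  qw <- windows[windows$qualify, , drop = FALSE]
  if (nrow(qw) == 0) return(hits)
  for (i in seq_len(nrow(qw))) {
    rows <- scored_rows[[qw$chrom[i]]]
    inside <- rows[qw$first[i]:qw$last[i]]
    hits[inside] <- hits[inside] | exceed[inside]
  }
  hits
}

#' Intersection decision rule producing the candidate table
#'
#' A SNP is called under recent positive selection in a population iff it is
#' a haplotype-test hit there (iHS within the population, or xpEHH with the
#' score sign attributing the signal to that population), has a high FST in
#' at least `fst_k` pairwise comparisons involving the population, and is
#' exonic. PBS is corroborative by default: the value and its top-quantile
#' flag are attached, and a candidate lacking a high PBS is reported with
#' `pbs_high = FALSE` rather than vetoed; `pbs_strict = TRUE` makes PBS
#' gating.
#'
#' @param sites site table (chrom, pos, ref, alt, ...) all inputs align to.
#' @param ihs_hits named list (population -> logical vector per site).
#' @param xpehh_hits list of entries, each a list with `pops = c(a, b)`,
#'   `hits` (logical per site) and `score` (signed standardized score used
#'   for attribution: positive attributes to `a`, negative to `b`).
#' @param fst_flags list of entries, each a list with `pops = c(a, b)` and
#'   `flags` (logical per site).
#' @param pbs_records named list (test population -> list with `pbs` values
#'   and `high` flags per site), or `NULL`.
#' @param exonic logical vector per site.
#' @param fst_k number of corroborating FST pairs required (default 1).
#' @param pbs_strict make a high PBS a requirement for the final call.
#' @return data.frame of class `candidate_table`, one row per
#'   (site, population) with any evidence: `chrom`, `pos`, `ref`, `alt`,
#'   `population`, `ihs_hit`, `xpehh_hit`, `fst_high`, `pbs`, `pbs_high`,
#'   `exonic`, `final_call`.
#' @export
decide <- function(sites, ihs_hits = list(), xpehh_hits = list(),
                   fst_flags = list(), pbs_records = NULL, exonic,
                   fst_k = 1, pbs_strict = FALSE) {
  ns <- nrow(sites)
  stopifnot(length(exonic) == ns)
  for (h in ihs_hits) stopifnot(length(h) == ns)
  pops <- unique(c(names(ihs_hits),
                   unlist(lapply(xpehh_hits, `[[`, "pops")),
                   unlist(lapply(fst_flags, `[[`, "pops"))))
  rows <- list()
  for (p in pops) {
    ihs_p <- if (p %in% names(ihs_hits)) ihs_hits[[p]] else rep(FALSE, ns)
    xp_p <- rep(FALSE, ns)
    for (e in xpehh_hits) {
      if (!(p %in% e$pops)) next
      stopifnot(length(e$hits) == ns, length(e$score) == ns)
      side <- if (p == e$pops[1]) 1 else -1
      attributed <- e$hits & !is.na(e$score) & (side * e$score > 0)
      xp_p <- xp_p | attributed
    }
    nfst <- rep(0L, ns)
    involved <- 0L
    for (e in fst_flags) {
      if (!(p %in% e$pops)) next
      stopifnot(length(e$flags) == ns)
      involved <- involved + 1L
      nfst <- nfst + as.integer(e$flags)
    }
    fst_p <- nfst >= min(fst_k, max(involved, 1L))
    if (involved == 0L) fst_p <- rep(FALSE, ns)
    pbs_val <- rep(NA_real_, ns)
    pbs_hi <- rep(NA, ns)
    if (!is.null(pbs_records) && p %in% names(pbs_records)) {
      pr <- pbs_records[[p]]
      pbs_val <- pr$pbs
      pbs_hi <- pr$high
    }
    call <- (ihs_p | xp_p) & fst_p & exonic
    if (pbs_strict) call <- call & !is.na(pbs_hi) & pbs_hi
    keep <- ihs_p | xp_p
    if (!any(keep)) next
    rows[[p]] <- data.frame(
      chrom = sites$chrom[keep], pos = sites$pos[keep],
      ref = sites$ref[keep], alt = sites$alt[keep],
      population = p, ihs_hit = ihs_p[keep], xpehh_hit = xp_p[keep],
      fst_high = fst_p[keep], pbs = pbs_val[keep], pbs_high = pbs_hi[keep],
      exonic = exonic[keep], final_call = call[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), population = character(0),
               ihs_hit = logical(0), xpehh_hit = logical(0),
               fst_high = logical(0), pbs = numeric(0), pbs_high = logical(0),
               exonic = logical(0), final_call = logical(0))
  out <- out[order(out$chrom, out$pos, out$population), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Join candidate SNPs with an association annotation table
#'
#' Left join keyed on `chrom + pos + ref + alt` (allele order-insensitive on
#' ref/alt swaps is NOT applied; keys must match the candidate coding).
#' Unmatched candidates keep empty annotation; duplicate association keys
#' are all kept, with a warning.
#'
#' @param candidates a [decide()] table.
#' @param assoc data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `cancer_types`.
#' @return the candidate table with `gene` and `cancer_types` columns.
#' @export
annotate_candidates <- function(candidates, assoc) {
  if (is.null(assoc) || nrow(assoc) == 0 || nrow(candidates) == 0) {
    candidates$gene <- character(nrow(candidates))
    candidates$cancer_types <- character(nrow(candidates))
    return(candidates)
  }
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gene", "cancer_types")
                %in% names(assoc)))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  ak <- key(assoc)
  if (anyDuplicated(ak))
    warning("duplicate association keys; keeping all matching rows")
  ck <- key(candidates)
  hitlist <- split(seq_along(ak), ak)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    m <- hitlist[[ck[i]]]
    if (is.null(m)) {
      r <- candidates[i, , drop = FALSE]
      r$gene <- ""
      r$cancer_types <- ""
      out[[length(out) + 1L]] <- r
    } else {
      for (j in m) {
        r <- candidates[i, , drop = FALSE]
        r$gene <- assoc$gene[j]
        r$cancer_types <- assoc$cancer_types[j]
        out[[length(out) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- class(candidates)
  res
}
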