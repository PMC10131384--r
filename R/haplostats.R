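#' Extended haplotype homozygosity around a core site
#'
#' EHH at extent `j` is the probability that two randomly chosen carrier
#' haplotypes are identical over the interval between the core and `j`;
#' equivalently `sum_h C(k_h, 2) / C(n, 2)` over the sub-haplotype groups at
#' `j`. The curve starts at 1 at the core and is extended in each direction
#' until it first drops below `cutoff` (that point is recorded, then the arm
#' stops) or the chromosome edge is reached.
#'
#' @param m a [haplo_matrix()].
#' @param core site index (1-based column of `m`).
#' @param allele which carrier set: `"derived"` (entry 1), `"ancestral"`
#'   (entry 0) or `"pooled"` (all haplotypes, as used by xpEHH).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param max_gap inter-site physical gap (bp) beyond which extension is
#'   abandoned and the arm is flagged; 0 disables the check.
#' @return object of class `ehh_curve`: a list with `core`, `allele`,
#'   `n_carriers`, an `arms` data.frame (`side`, `site`, `pos`, `ehh`) and
#'   per-arm `edge`/`gap` flags.
#' @export
ehh <- function(m, core, allele = c("derived", "ancestral", "pooled"),
                cutoff = 0.05, max_gap = 0) {
  allele <- match.arg(allele)
  stopifnot(core >= 1, core <= n_sites(m))
  col <- m$entries[, core]
  carriers <- switch(allele,
                     derived = which(col == 1L),
                     ancestral = which(col == 0L),
                     pooled = seq_along(col))
  if (length(carriers) < 2)
    stop("monomorphic core: fewer than 2 carriers of the ", allele,
         " allele at site ", core)
  # the walk never leaves the core's chromosome
  j <- which(m$sites$chrom == m$sites$chrom[core])
  r <- .ehh_curve_cpp(m$entries[, j, drop = FALSE], m$sites$pos[j],
                      match(core, j) - 1L, carriers - 1L, cutoff, max_gap)
  arms <- rbind(
    data.frame(side = "left", site = j[rev(r$left_idx) + 1L],
               ehh = rev(r$left_ehh)),
    data.frame(side = "right", site = j[r$right_idx + 1L],
               ehh = r$right_ehh))
  arms$pos <- m$sites$pos[arms$site]
  structure(list(core = core, allele = allele, n_carriers = length(carriers),
                 cutoff = cutoff, arms = arms,
                 edge = c(left = r$left_edge, right = r$right_edge),
                 gap = c(left = r$left_gap, right = r$right_gap)),
            class = "ehh_curve")
}

#' Integrated EHH (iHH) of a curve
#'
#' Trapezoidal integral of EHH against physical position, summed over the
#' upstream and downstream arms. Only trapezoids whose both endpoints have
#' EHH at or above the cutoff contribute; the first below-cutoff point is
#' excluded (no interpolation). If either arm was truncated by the
#' chromosome edge before reaching the cutoff the score is suppressed
#' (`NA` with attribute `reason = "edge"`; likewise `"gap"`).
#'
#' @param curve an [ehh()] curve.
#' @param cutoff override of the curve's own cutoff.
#' @return area in bp, or `NA` with a `reason` attribute.
#' @export
ihh <- function(curve, cutoff = NULL) {
  stopifnot(inherits(curve, "ehh_curve"))
  if (is.null(cutoff)) cutoff <- curve$cutoff
  if (any(curve$gap)) return(structure(NA_real_, reason = "gap"))
  if (any(curve$edge)) return(structure(NA_real_, reason = "edge"))
  total <- 0
  for (side in c("left", "right")) {
    a <- curve$arms[curve$arms$side == side, , drop = FALSE]
    # order outward from the core
    if (side == "left") a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
    if (nrow(a) < 2) next
    for (k in seq_len(nrow(a) - 1L)) {
      if (a$ehh[k] < cutoff || a$ehh[k + 1L] < cutoff) break
      total <- total + 0.5 * (a$ehh[k] + a$ehh[k + 1L]) *
        abs(a$pos[k + 1L] - a$pos[k])
    }
  }
  total
}

#' Construct a per-SNP score track
#'
#' The common container for per-SNP statistics (iHS, xpEHH, FST): a
#' data.frame with site coordinates, frequencies, the raw value, a
#' `standardized` column (NA until [standardize()]) and a per-SNP reason
#' code. Mostly used internally by the scan functions; exported so tracks
#' can be built directly from externally computed scores.
#'
#' @param sites data.frame with `chrom`, `pos`, `derived_freq`, `maf`.
#' @param raw numeric scores (NA where undefined).
#' @param reason character reason codes ("ok" where defined).
#' @param statistic statistic name.
#' @param pops population label(s).
#' @return a `score_track` data.frame.
#' @export
new_score_track <- function(sites, raw, reason, statistic, pops) {
  df <- data.frame(chrom = sites$chrom, pos = sites$pos,
                   derived_freq = sites$derived_freq, maf = sites$maf,
                   raw = raw, standardized = NA_real_,
                   reason = reason, stringsAsFactors = FALSE)
  structure(df, statistic = statistic, pops = pops,
            class = c("score_track", "data.frame"))
}

#' Genome scan of unstandardized iHS within one population
#'
#' Per qualifying core SNP, unstandardized
#' `iHS = ln(iHH_ancestral / iHH_derived)`. Cores are skipped with a reason
#' code when either allele class has fewer than `min_carriers` carriers
#' (`"monomorphic"`), the EHH curve runs off the chromosome before reaching
#' the cutoff (`"edge"`), an inter-site gap exceeds `max_gap` before the
#' cutoff (`"gap"`), or either integrated area is zero (`"zero_area"`).
#'
#' @param m polarized, MAF-filtered [haplo_matrix()].
#' @param cutoff EHH truncation threshold.
#' @param max_gap maximum tolerated inter-site gap in bp.
#' @param min_carriers minimum carriers per allele class (default 2).
#' @return a `score_track` data.frame (`chrom`, `pos`, `derived_freq`, `maf`,
#'   `raw`, `standardized`, `reason`).
#' @export
ihs_scan <- function(m, cutoff = 0.05, max_gap = 200000, min_carriers = 2) {
  stopifnot(inherits(m, "haplo_matrix"))
  ns <- n_sites(m)
  score <- rep(NA_real_, ns)
  reason <- integer(ns)
  # chromosomes are scanned independently; EHH never crosses a boundary
  for (ch in unique(m$sites$chrom)) {
    j <- which(m$sites$chrom == ch)
    r <- .ihs_scan_cpp(m$entries[, j, drop = FALSE], m$sites$pos[j],
                       cutoff, max_gap, as.integer(min_carriers))
    score[j] <- r$score
    reason[j] <- r$reason
  }
  new_score_track(m$sites, score, .reason_from_code(reason),
                  statistic = "ihs", pops = m$pop)
}

#' Cross-population xpEHH scan (unstandardized)
#'
#' iHH is computed over all haplotypes (alleles pooled) in each population
#' separately; the truncation extent in both populations is set by where the
#' combined two-population EHH first falls below the cutoff. Unstandardized
#' `xpEHH = ln(iHH_a / iHH_b)`: positive values mean longer haplotypes
#' (candidate selection) in population `a`.
#'
#' @param ma,mb [haplo_matrix()] objects sharing an identical site list.
#' @param cutoff EHH truncation threshold on the combined curve.
#' @param max_gap maximum tolerated inter-site gap in bp.
#' @param pooled_maf_min cores with pooled (both populations) MAF below this
#'   are masked with reason `"maf"`.
#' @return a `score_track` data.frame.
#' @export
xpehh_scan <- function(ma, mb, cutoff = 0.05, max_gap = 200000,
                       pooled_maf_min = 0.05) {
  check_shared_sites(ma, mb)
  ns <- n_sites(ma)
  raw <- rep(NA_real_, ns)
  rcode <- integer(ns)
  for (ch in unique(ma$sites$chrom)) {
    j <- which(ma$sites$chrom == ch)
    r <- .xpehh_scan_cpp(ma$entries[, j, drop = FALSE],
                         mb$entries[, j, drop = FALSE],
                         ma$sites$pos[j], cutoff, max_gap)
    raw[j] <- r$score
    rcode[j] <- r$reason
  }
  reason <- .reason_from_code(rcode)
  na <- nrow(ma$entries); nb <- nrow(mb$entries)
  f_pool <- (na * ma$sites$derived_freq + nb * mb$sites$derived_freq) / (na + nb)
  maf_pool <- pmin(f_pool, 1 - f_pool)
  low <- maf_pool < pooled_maf_min
  raw[low] <- NA_real_
  reason[low] <- "maf"
  sites <- ma$sites
  sites$derived_freq <- f_pool
  sites$maf <- maf_pool
  new_score_track(sites, raw, reason, statistic = "xpehh",
                  pops = c(ma$pop, mb$pop))
}

#' Standardize a score track within frequency bins
#'
#' `standardized = (raw - bin mean) / bin sd`, with bins defined on the core
#' SNP's derived-allele frequency over `[0, 1]` in `n_bins` equal widths
#' (`bin_variable = "none"` uses a single genome-wide bin, the default
#' treatment for xpEHH). Population moments (divide by n) are used, so the
#' per-bin mean-0 / variance-1 identity is exact. Occupied bins with fewer
#' than `min_bin_size` scores are merged with their nearest neighbour; a bin
#' with zero standard deviation leaves its scores undefined
#' (`"constant_bin"`).
#'
#' @param track a `score_track` with raw values.
#' @param n_bins number of equal-width frequency bins (default 100).
#' @param bin_variable `"derived_freq"` or `"none"`.
#' @param min_bin_size minimum scores per retained bin (default 20).
#' @return the track with `standardized` filled in; the per-bin table
#'   (bounds, n, mean, sd) is attached as attribute `"bins"`.
#' @export
standardize <- function(track, n_bins = 100,
                        bin_variable = c("derived_freq", "none"),
                        min_bin_size = 20) {
  bin_variable <- match.arg(bin_variable)
  ok <- track$reason == "ok" & !is.na(track$raw)
  if (sum(ok) == 0) {
    attr(track, "bins") <- data.frame()
    return(track)
  }
  x <- track$raw[ok]
  if (bin_variable == "none" || n_bins == 1) {
    bin <- rep(1L, sum(ok))
    bounds <- data.frame(lower = 0, upper = 1)
  } else {
    f <- track$derived_freq[ok]
    bin <- pmin(pmax(ceiling(f * n_bins), 1L), n_bins)
    # merge sparse occupied bins with their nearest occupied neighbour
    tab <- table(factor(bin, levels = seq_len(n_bins)))
    occ <- which(tab > 0)
    grp <- merge_sparse_bins(as.integer(tab[occ]), occ, min_bin_size)
    merged_of_bin <- integer(n_bins)
    merged_of_bin[occ] <- grp
    bin <- merged_of_bin[bin]
    width <- 1 / n_bins
    bounds <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
      b <- occ[grp == g]
      data.frame(lower = (min(b) - 1) * width, upper = max(b) * width)
    }))
    bin <- match(bin, sort(unique(grp)))
  }
  nb <- nrow(bounds)
  mu <- tapply(x, factor(bin, levels = seq_len(nb)), mean)
  # population moments: divide by n, not n - 1
  v <- tapply(x, factor(bin, levels = seq_len(nb)),
              function(z) mean((z - mean(z))^2))
  sdv <- sqrt(v)
  std <- (x - mu[bin]) / sdv[bin]
  const <- !is.na(sdv[bin]) & sdv[bin] == 0
  std[const] <- NA_real_
  track$standardized <- NA_real_
  track$standardized[ok] <- as.numeric(std)
  reason <- track$reason
  idx_ok <- which(ok)
  reason[idx_ok[const]] <- "constant_bin"
  track$reason <- reason
  attr(track, "bins") <- data.frame(bounds,
                                    n = as.integer(table(factor(bin, levels = seq_len(nb)))),
                                    mean = as.numeric(mu), sd = as.numeric(sdv))
  attr(track, "n_bins_requested") <- n_bins
  track
}
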