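#' Weir & Cockerham (1984) FST at one site from diploid genotypes
#'
#' Two-population variance-component estimator: `a` (among populations),
#' `b` (among individuals within populations), `c` (within individuals),
#' and `fst = a / (a + b + c)`. Small-sample estimates may be negative;
#' a site monomorphic across both populations is undefined.
#'
#' @param geno1,geno2 integer vectors of derived-allele dosages (0/1/2), one
#'   entry per diploid individual.
#' @return list with `a`, `b`, `c`, `fst` and `reason` (`"ok"` or
#'   `"monomorphic"`).
#' @export
wc_fst <- function(geno1, geno2) {
  stopifnot(length(geno1) >= 2, length(geno2) >= 2,
            all(geno1 %in% 0:2), all(geno2 %in% 0:2))
  comp <- wc_fst_components(
    p1 = mean(geno1) / 2, p2 = mean(geno2) / 2,
    h1 = mean(geno1 == 1L), h2 = mean(geno2 == 1L),
    n1 = length(geno1), n2 = length(geno2))
  list(a = comp$a, b = comp$b, c = comp$c, fst = comp$fst,
       reason = if (is.na(comp$fst)) "monomorphic" else "ok")
}

# vectorized two-population Weir & Cockerham (1984) components
wc_fst_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- ifelse(denom == 0, NA_real_, a / denom)
  list(a = a, b = b, c = cc, fst = fst)
}

#' Per-site Weir & Cockerham FST scan between two populations
#'
#' Haplotype pairs are recombined into diploid genotypes (rows `2i-1, 2i`
#' become individual `i`) and the 1984 two-population estimator is evaluated
#' per site. Undefined (monomorphic) sites carry reason codes.
#'
#' @param ma,mb [haplo_matrix()] objects sharing an identical site list,
#'   with an even number of haplotype rows each.
#' @return a `score_track` data.frame with `raw` = FST; the variance
#'   components are attached as columns `a`, `b`, `c`.
#' @export
fst_scan <- function(ma, mb) {
  check_shared_sites(ma, mb)
  g1 <- genotype_dosage(ma)
  g2 <- genotype_dosage(mb)
  comp <- wc_fst_components(
    p1 = colMeans(g1) / 2, p2 = colMeans(g2) / 2,
    h1 = colMeans(g1 == 1L), h2 = colMeans(g2 == 1L),
    n1 = nrow(g1), n2 = nrow(g2))
  na <- nrow(ma$entries); nb <- nrow(mb$entries)
  f_pool <- (na * ma$sites$derived_freq + nb * mb$sites$derived_freq) / (na + nb)
  sites <- ma$sites
  sites$derived_freq <- f_pool
  sites$maf <- pmin(f_pool, 1 - f_pool)
  tr <- new_score_track(sites, comp$fst,
                        ifelse(is.na(comp$fst), "monomorphic", "ok"),
                        statistic = "fst", pops = c(ma$pop, mb$pop))
  tr$a <- comp$a
  tr$b <- comp$b
  tr$c <- comp$c
  tr
}

# diploid derived-allele dosage matrix (individuals x sites)
genotype_dosage <- function(m) {
  e <- m$entries
  if (nrow(e) %% 2L != 0L)
    stop("odd haplotype count: cannot pair into diploid individuals")
  i1 <- seq(1L, nrow(e), by = 2L)
  e[i1, , drop = FALSE] + e[i1 + 1L, , drop = FALSE]
}

#' Frequency-binned empirical FST outlier flags
#'
#' Because FST and allele frequency are strongly correlated, FST values are
#' contrasted only against their own frequency class: sites are binned by
#' pooled MAF over `[0, 0.5]` in bins of `bin_width`, the per-bin threshold
#' is the empirical `(1 - quantile)` percentile, and a site is flagged iff
#' its FST is strictly greater than its bin's threshold (ties never flag).
#' Bins with fewer than `min_bin_size` defined sites are merged with their
#' nearest neighbour.
#'
#' @param fst numeric vector of per-site FST (NA = undefined).
#' @param pooled_maf per-site pooled MAF in `[0, 0.5]`.
#' @param bin_width frequency bin width (default 0.05).
#' @param quantile upper-tail mass defining an outlier (default 0.05).
#' @param min_bin_size minimum sites per retained bin (default 20).
#' @return list with `flags` (logical per site) and `thresholds` (per-bin
#'   table: bounds, n, threshold).
#' @export
binned_fst_flags <- function(fst, pooled_maf, bin_width = 0.05,
                             quantile = 0.05, min_bin_size = 20) {
  stopifnot(length(fst) == length(pooled_maf))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  ok <- !is.na(fst)
  n_bins <- max(1L, ceiling(0.5 / bin_width))
  bin_all <- pmin(pmax(ceiling(pooled_maf / bin_width), 1L), n_bins)
  tab <- table(factor(bin_all[ok], levels = seq_len(n_bins)))
  occ <- which(tab > 0)
  if (length(occ) == 0)
    return(list(flags = rep(FALSE, length(fst)),
                thresholds = data.frame()))
  grp <- merge_sparse_bins(as.integer(tab[occ]), occ, min_bin_size)
  merged_of_bin <- integer(n_bins)
  merged_of_bin[occ] <- grp
  gids <- sort(unique(grp))
  flags <- rep(FALSE, length(fst))
  thr <- data.frame(lower = numeric(0), upper = numeric(0),
                    n = integer(0), threshold = numeric(0))
  for (g in gids) {
    bins_g <- occ[grp == g]
    in_g <- ok & merged_of_bin[bin_all] == g
    th <- as.numeric(stats::quantile(fst[in_g], probs = 1 - quantile,
                                     names = FALSE, type = 1))
    flags[in_g] <- fst[in_g] > th
    thr <- rbind(thr, data.frame(lower = (min(bins_g) - 1) * bin_width,
                                 upper = min(max(bins_g) * bin_width, 0.5),
                                 n = sum(in_g), threshold = th))
  }
  list(flags = flags, thresholds = thr)
}

# shared sparse-bin merging: greedily fold any group under the floor into its
# nearest occupied neighbour (tie towards lower frequency); deterministic
merge_sparse_bins <- function(cnt, occ, min_bin_size) {
  grp <- seq_along(occ)
  repeat {
    ids <- sort(unique(grp))
    if (length(ids) == 1) break
    gcnt <- vapply(ids, function(g) sum(cnt[grp == g]), numeric(1))
    small <- ids[gcnt < min_bin_size]
    if (length(small) == 0) break
    g <- small[1]
    i <- match(g, ids)
    nb <- if (i == 1) ids[2]
          else if (i == length(ids)) ids[length(ids) - 1]
          else {
            dl <- min(occ[grp == g]) - max(occ[grp == ids[i - 1]])
            dr <- min(occ[grp == ids[i + 1]]) - max(occ[grp == g])
            if (dl <= dr) ids[i - 1] else ids[i + 1]
          }
    grp[grp == g] <- nb
  }
  grp
}

#' Population branch statistic from three pairwise FST tracks
#'
#' `T = -ln(1 - FST)` with FST clamped into `[0, 1 - 1e-12]` (negative
#' estimates clamped to 0) before the transform, then
#' `PBS = (T_test,sister + T_test,outgroup - T_sister,outgroup) / 2`.
#' All six population-role assignments of a three-way comparison are
#' obtained by relabeling the inputs. A site with any undefined FST in the
#' triplet is undefined.
#'
#' @param fst_ts per-site FST test vs sister.
#' @param fst_to per-site FST test vs outgroup.
#' @param fst_so per-site FST sister vs outgroup.
#' @param test,sister,outgroup population labels (metadata only).
#' @return data.frame with `T_ts`, `T_to`, `T_so`, `pbs` and the labels as
#'   attributes `"test"`, `"sister"`, `"outgroup"`.
#' @export
pbs <- function(fst_ts, fst_to, fst_so, test = "test", sister = "sister",
                outgroup = "outgroup") {
  stopifnot(length(fst_ts) == length(fst_to),
            length(fst_ts) == length(fst_so))
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-12))
  T_ts <- tt(fst_ts); T_to <- tt(fst_to); T_so <- tt(fst_so)
  out <- data.frame(T_ts = T_ts, T_to = T_to, T_so = T_so,
                    pbs = (T_ts + T_to - T_so) / 2)
  attr(out, "test") <- test
  attr(out, "sister") <- sister
  attr(out, "outgroup") <- outgroup
  out
}

#' Genome-wide top-quantile PBS flags
#'
#' Threshold is the empirical `(1 - quantile)` percentile of the defined PBS
#' values for one comparison; a site is flagged iff strictly above it.
#'
#' @param pbs_values numeric vector (NA = undefined).
#' @param quantile upper-tail mass (default 0.05).
#' @param min_n below this many defined values a warning is issued (the
#'   threshold is still computed).
#' @return list with `flags` and `threshold`.
#' @export
pbs_top_flags <- function(pbs_values, quantile = 0.05, min_n = 100) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  ok <- !is.na(pbs_values)
  if (sum(ok) < min_n)
    warning("only ", sum(ok), " defined PBS values; threshold is unstable")
  if (sum(ok) == 0)
    return(list(flags = rep(FALSE, length(pbs_values)), threshold = NA_real_))
  th <- as.numeric(stats::quantile(pbs_values[ok], probs = 1 - quantile,
                                   names = FALSE, type = 1))
  flags <- !is.na(pbs_values) & pbs_values > th
  list(flags = flags, threshold = th)
}
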