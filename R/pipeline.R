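#' Configuration for the end-to-end selection scan
#'
#' Defaults reproduce the scan's canonical thresholds: MAF >= 0.05,
#' |standardized score| > 2, 51-SNP windows, top 1% windows, top 5%
#' frequency-binned FST, top 5% PBS.
#'
#' @param outgroup population label used as the PBS outgroup, or `NULL` to
#'   skip PBS (it is never computed for comparisons involving the outgroup).
#' @param maf_min minor-allele-frequency floor.
#' @param ehh_cutoff EHH truncation threshold.
#' @param max_gap maximum tolerated inter-site gap (bp) during EHH extension.
#' @param ihs_bins derived-allele-frequency bins for iHS standardization.
#' @param xpehh_bins bins for xpEHH standardization (1 = genome-wide).
#' @param window_size SNPs per sliding window (odd).
#' @param score_cutoff absolute standardized-score threshold.
#' @param window_quantile upper-tail mass for qualifying windows.
#' @param fst_quantile upper-tail mass for high FST within a frequency bin.
#' @param fst_bin_width pooled-MAF bin width for the FST thresholds.
#' @param pbs_quantile upper-tail mass for high PBS.
#' @param fst_k corroborating FST pairs required for a call (default 1;
#'   `Inf` = all pairs involving the population).
#' @param pbs_strict make a high PBS gating rather than corroborative.
#' @param min_bin_size merge frequency bins with fewer sites than this.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(outgroup = NULL, maf_min = 0.05, ehh_cutoff = 0.05,
                        max_gap = 200000, ihs_bins = 100, xpehh_bins = 1,
                        window_size = 51, score_cutoff = 2,
                        window_quantile = 0.01, fst_quantile = 0.05,
                        fst_bin_width = 0.05, pbs_quantile = 0.05,
                        fst_k = 1, pbs_strict = FALSE, min_bin_size = 20) {
  for (q in c(window_quantile, fst_quantile, pbs_quantile))
    if (q <= 0 || q >= 1) stop("quantiles must be in (0, 1)")
  if (window_size %% 2 != 1) stop("window_size must be odd")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  structure(as.list(environment())[c(
    "outgroup", "maf_min", "ehh_cutoff", "max_gap", "ihs_bins", "xpehh_bins",
    "window_size", "score_cutoff", "window_quantile", "fst_quantile",
    "fst_bin_width", "pbs_quantile", "fst_k", "pbs_strict", "min_bin_size")],
    class = "scan_config")
}

subset_sites <- function(m, keep) {
  haplo_matrix(m$entries[, keep, drop = FALSE],
               m$sites[keep, c("chrom", "pos", "ref", "alt", "aa")],
               sample_ids = m$sample_ids, pop = m$pop, polarized = m$polarized)
}

#' Run the full recent-selection scan
#'
#' Orchestrates the pipeline on polarized per-population haplotype matrices
#' sharing one site list: pooled-MAF site filter, per-population iHS and
#' per-pair xpEHH scans with frequency-bin standardization, 51-SNP window
#' outlier clustering, per-pair Weir & Cockerham FST with frequency-binned
#' top-quantile flags, PBS per test/sister/outgroup assignment, exon
#' restriction and the intersection decision rule. Every empirical threshold
#' used is collected into a thresholds report.
#'
#' @param matrices named list of polarized [haplo_matrix()] objects sharing
#'   an identical site list.
#' @param exons a [region_set()] of exon intervals.
#' @param config a [scan_config()].
#' @param assoc optional SNP association table for [annotate_candidates()].
#' @param outdir if non-NULL, per-stage TSVs (with `#`-prefixed metadata
#'   echoing the resolved configuration) are written here.
#' @return list with `candidates`, `sites` (the filtered shared site list
#'   with exonic flags), `tracks` (standardized score tracks), `fst`,
#'   `pbs`, `windows` and `thresholds`.
#' @export
run_scan_pipeline <- function(matrices, exons, config = scan_config(),
                              assoc = NULL, outdir = NULL) {
  stopifnot(inherits(config, "scan_config"), length(matrices) >= 2)
  pops <- names(matrices)
  if (is.null(pops) || any(!nzchar(pops)))
    stop("matrices must be a named list (population labels)")
  m1 <- matrices[[1]]
  for (m in matrices) check_shared_sites(m1, m)

  # shared site list: biallelic SNPs with pooled MAF >= maf_min
  nh <- vapply(matrices, n_haplotypes, numeric(1))
  fpool <- Reduce(`+`, Map(function(m, w) w * m$sites$derived_freq,
                           matrices, nh)) / sum(nh)
  keep <- pmin(fpool, 1 - fpool) >= config$maf_min
  matrices <- lapply(matrices, subset_sites, keep = keep)
  sites <- matrices[[1]]$sites
  ns <- nrow(sites)
  thresholds <- list()

  # per-population iHS (cores additionally need within-population MAF)
  ihs_tracks <- list()
  ihs_hits <- list()
  windows_all <- list()
  for (p in pops) {
    tr <- ihs_scan(matrices[[p]], cutoff = config$ehh_cutoff,
                   max_gap = config$max_gap)
    low <- matrices[[p]]$sites$maf < config$maf_min
    tr$raw[low] <- NA_real_
    tr$reason[low] <- "maf"
    tr <- standardize(tr, n_bins = config$ihs_bins,
                      bin_variable = "derived_freq",
                      min_bin_size = config$min_bin_size)
    w <- window_counts(tr, config$window_size, config$score_cutoff)
    w <- top_window_flags(w, config$window_quantile)
    ihs_hits[[p]] <- haplotype_hits(tr, w, config$score_cutoff)
    ihs_tracks[[p]] <- tr
    windows_all[[paste0("ihs_", p)]] <- w
    thresholds[[paste0("ihs_window_", p)]] <- attr(w, "threshold")
  }

  # per-pair xpEHH
  xp_tracks <- list()
  xpehh_hits <- list()
  pair_names <- character(0)
  if (length(pops) >= 2) {
    for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops))) {
      a <- pops[i]; b <- pops[j]
      nm <- paste0(a, "_vs_", b)
      pair_names <- c(pair_names, nm)
      tr <- xpehh_scan(matrices[[a]], matrices[[b]],
                       cutoff = config$ehh_cutoff, max_gap = config$max_gap,
                       pooled_maf_min = config$maf_min)
      tr <- standardize(tr, n_bins = config$xpehh_bins,
                        bin_variable = if (config$xpehh_bins > 1)
                          "derived_freq" else "none",
                        min_bin_size = config$min_bin_size)
      w <- window_counts(tr, config$window_size, config$score_cutoff)
      w <- top_window_flags(w, config$window_quantile)
      xpehh_hits[[nm]] <- list(pops = c(a, b),
                               hits = haplotype_hits(tr, w,
                                                     config$score_cutoff),
                               score = tr$standardized)
      xp_tracks[[nm]] <- tr
      windows_all[[paste0("xpehh_", nm)]] <- w
      thresholds[[paste0("xpehh_window_", nm)]] <- attr(w, "threshold")
    }
  }

  # per-pair FST with frequency-binned outlier flags
  fst_tracks <- list()
  fst_flags <- list()
  for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops))) {
    a <- pops[i]; b <- pops[j]
    nm <- paste0(a, "_vs_", b)
    tr <- fst_scan(matrices[[a]], matrices[[b]])
    bf <- binned_fst_flags(tr$raw, tr$maf, bin_width = config$fst_bin_width,
                           quantile = config$fst_quantile,
                           min_bin_size = config$min_bin_size)
    fst_flags[[nm]] <- list(pops = c(a, b), flags = bf$flags)
    fst_tracks[[nm]] <- tr
    thresholds[[paste0("fst_bins_", nm)]] <- bf$thresholds
  }

  # PBS per test population (outgroup comparisons are never defined)
  pbs_records <- NULL
  pbs_tables <- list()
  if (!is.null(config$outgroup) && config$outgroup %in% pops &&
      length(pops) >= 3) {
    og <- config$outgroup
    inner <- setdiff(pops, og)
    get_fst <- function(a, b) {
      nm1 <- paste0(a, "_vs_", b); nm2 <- paste0(b, "_vs_", a)
      if (nm1 %in% names(fst_tracks)) fst_tracks[[nm1]]$raw
      else fst_tracks[[nm2]]$raw
    }
    pbs_records <- list()
    for (test in inner) {
      best_pbs <- rep(NA_real_, ns)
      any_high <- rep(FALSE, ns)
      for (sister in setdiff(inner, test)) {
        tab <- pbs(get_fst(test, sister), get_fst(test, og),
                   get_fst(sister, og),
                   test = test, sister = sister, outgroup = og)
        fl <- pbs_top_flags(tab$pbs, quantile = config$pbs_quantile)
        nm <- paste0("pbs_", test, "_given_", sister)
        pbs_tables[[nm]] <- tab
        thresholds[[nm]] <- fl$threshold
        best_pbs <- pmax(best_pbs, tab$pbs, na.rm = TRUE)
        any_high <- any_high | fl$flags
      }
      pbs_records[[test]] <- list(pbs = best_pbs, high = any_high)
    }
  }

  exonic <- annotate_regions(sites, exons)
  cand <- decide(sites, ihs_hits = ihs_hits, xpehh_hits = xpehh_hits,
                 fst_flags = fst_flags, pbs_records = pbs_records,
                 exonic = exonic, fst_k = config$fst_k,
                 pbs_strict = config$pbs_strict)
  cand <- annotate_candidates(cand, assoc)

  res <- list(candidates = cand,
              sites = cbind(sites, exonic = exonic),
              tracks = c(lapply(ihs_tracks, identity),
                         stats::setNames(xp_tracks,
                                         paste0("xpehh_", names(xp_tracks)))),
              fst = fst_tracks, pbs = pbs_tables, windows = windows_all,
              thresholds = thresholds, config = config)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

config_echo <- function(config) {
  vals <- vapply(config, function(v)
    paste(format(v, trim = TRUE), collapse = ","), character(1))
  paste0("# ", names(config), "=", vals)
}

write_tsv_meta <- function(df, path, meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the per-stage TSV outputs of a pipeline run
#'
#' Every file starts with `#`-prefixed metadata echoing the resolved
#' configuration, so a run is reproducible from its outputs alone.
#'
#' @param res result list of [run_scan_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- config_echo(res$config)
  write_tsv_meta(res$candidates, file.path(outdir, "candidates.tsv"), meta)
  for (nm in names(res$tracks))
    write_tsv_meta(res$tracks[[nm]],
                   file.path(outdir, paste0("track_", nm, ".tsv")), meta)
  for (nm in names(res$fst))
    write_tsv_meta(res$fst[[nm]],
                   file.path(outdir, paste0("fst_", nm, ".tsv")), meta)
  scalar <- vapply(res$thresholds, function(x) !is.data.frame(x), logical(1))
  if (any(scalar))
    write_tsv_meta(data.frame(name = names(res$thresholds)[scalar],
                              threshold = unlist(res$thresholds[scalar])),
                   file.path(outdir, "thresholds.tsv"), meta)
  for (nm in names(res$thresholds)[!scalar])
    write_tsv_meta(res$thresholds[[nm]],
                   file.path(outdir, paste0("thresholds_", nm, ".tsv")), meta)
  invisible(outdir)
}
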