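#' Concatenate per-chromosome simulations into one multi-chromosome cohort
#'
#' Selection-scan thresholds (top-percent windows, frequency-binned FST,
#' top-percent PBS) are empirical genome-wide distributions: a single
#' candidate region cannot supply its own background without the outlier
#' quantiles degenerating onto the signal itself. This helper merges
#' independent simulations — one per chromosome, distinct seeds — into one
#' cohort whose per-population matrices carry all chromosomes, so every
#' empirical threshold downstream is pooled across them.
#'
#' @param sims named list of [simulate_demes()] results; names become the
#'   chromosome labels. All simulations must share population labels and
#'   sample sizes.
#' @return list with `matrices` (multi-chromosome [haplo_matrix()] per
#'   population) and `truth` (the per-chromosome truth lists, re-labelled).
#' @export
concat_chromosomes <- function(sims) {
  stopifnot(length(sims) >= 1, !is.null(names(sims)), all(nzchar(names(sims))))
  pops <- names(sims[[1]]$matrices)
  for (s in sims)
    if (!identical(names(s$matrices), pops))
      stop("all simulations must share the same population labels")
  mats <- lapply(pops, function(p) {
    ents <- lapply(sims, function(s) s$matrices[[p]]$entries)
    if (length(unique(vapply(ents, nrow, integer(1)))) != 1)
      stop("all simulations must share sample sizes")
    sites <- do.call(rbind, lapply(names(sims), function(ch) {
      s <- sims[[ch]]$matrices[[p]]$sites
      s$chrom <- ch
      s[, c("chrom", "pos", "ref", "alt", "aa")]
    }))
    haplo_matrix(do.call(cbind, ents), sites,
                 sample_ids = sims[[1]]$matrices[[p]]$sample_ids,
                 pop = p, polarized = TRUE)
  })
  names(mats) <- pops
  truth <- lapply(names(sims), function(ch) {
    tt <- sims[[ch]]$truth
    tt$sites$chrom <- ch
    tt$chrom <- ch
    tt
  })
  names(truth) <- names(sims)
  list(matrices = mats, truth = truth)
}

#' The package's canonical synthetic selection-scan study
#'
#' Simulates the reference cohort used throughout the tests and analyses: a
#' small three-population genome (test, sister, outgroup; 500 diploids each,
#' 200 haplotypes sampled per deme) of three chromosomes — `chr1` (200 kb)
#' optionally carrying a hard sweep (s = 0.05, onset 200 generations before
#' present) at its centre, plus two neutral background chromosomes
#' (100 kb each) that populate the genome-wide empirical distributions.
#'
#' @param seed master seed; chromosome seeds are derived deterministically.
#' @param sweep simulate the sweep on chr1 (`TRUE`) or a fully neutral
#'   cohort (`FALSE`).
#' @param s selection coefficient of the planted sweep.
#' @return as [concat_chromosomes()]; additionally `focal_pos` and
#'   `sweep_deme` of the chr1 sweep (NA for neutral cohorts) at top level.
#' @export
simulate_study <- function(seed, sweep = TRUE, s = 0.05) {
  base <- function(L, chrom_seed, sw) {
    simulate_demes(sim_config(
      seq_length = L, seed = chrom_seed,
      sweep = if (sw) sweep_spec(deme = 1, pos = L / 2, s = s,
                                 onset = 200) else NULL))
  }
  sims <- list(
    chr1 = base(2e5, seed * 3L + 1L, sweep),
    chr2 = base(1e5, seed * 3L + 2L, FALSE),
    chr3 = base(1e5, seed * 3L + 3L, FALSE))
  out <- concat_chromosomes(sims)
  out$focal_pos <- out$truth$chr1$focal_pos
  out$sweep_deme <- out$truth$chr1$sweep_deme
  out
}

#' Exon model of the synthetic study
#'
#' Regular 2 kb exons on a 4 kb period (50% coding coverage, a gene-dense
#' regime) on every chromosome; the phase guarantees that the sweep's focal
#' position on chr1 is exonic, i.e. the planted selected variant is a coding
#' variant.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param period,width,offset tiling geometry in bp.
#' @return a [region_set()] labelled "exons".
#' @export
study_exon_model <- function(chrom_lengths = c(chr1 = 2e5, chr2 = 1e5,
                                               chr3 = 1e5),
                             period = 4000, width = 2000, offset = 2000) {
  iv <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    k <- 0:(chrom_lengths[[ch]] %/% period - 1)
    data.frame(chrom = ch, start = k * period + offset,
               end = k * period + offset + width, stringsAsFactors = FALSE)
  }))
  region_set(iv, label = "exons")
}
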