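#' Configuration for the forward Wright-Fisher simulator
#'
#' The simulator emulates the structure of multi-population phased human
#' cohorts at desk scale: a founding population evolves to mutation-drift
#' balance, daughter demes split off at configured times, demes exchange
#' migrants, and an optional hard selective sweep (genic selection with
#' fitness 1, 1+s, 1+2s) acts on a focal mutation planted in one deme.
#' Defaults are the scaled study conditions used throughout the package:
#' three demes (test, sister, outgroup) of 500 diploids, a 200 kb region
#' with a per-bp mutation rate of 1e-6 (theta ~ 0.002/bp, a genome-like
#' SNP density after MAF filtering) and recombination rate of 1.5e-6 per
#' generation (scaled up relative to a human map so haplotype homozygosity
#' decays well inside the region, while the sweep footprint of roughly
#' s / (r ln 2Ns) ~ 9 kb spans about one 51-SNP window and stays a small
#' fraction of the simulated genome), outgroup split 600 and sister split
#' 300
#' generations before present, and a sweep of s = 0.05 starting 250
#' generations before present at the centre of the region (still
#' segregating or freshly fixed at sampling time, the regime both
#' haplotype tests target).
#'
#' @param n_demes number of demes.
#' @param deme_size diploid population size N per deme.
#' @param split_generations integer vector, one entry per deme: generations
#'   before present at which the deme splits from its parent (entry for the
#'   founding deme is ignored; use 0).
#' @param parent_deme integer vector, the deme each daughter splits from.
#' @param migration_rate per-gene-copy per-generation probability that a
#'   parent is drawn from another (uniformly chosen) living deme.
#' @param seq_length region length in bp.
#' @param mu per-bp per-generation mutation rate (infinite-sites).
#' @param rec_rate per-bp per-generation recombination rate; crossover count
#'   per meiosis is Poisson with mean `rec_rate * seq_length`.
#' @param burn_in generations the founding deme evolves before the first
#'   split (default `4 * deme_size`).
#' @param sweep `NULL` for neutral, or a list with `deme` (1-based index),
#'   `pos` (focal bp), `s` (selection coefficient, >= 0) and `onset`
#'   (generations before present).
#' @param sample_sizes haplotypes sampled per deme (each <= 2 * deme_size).
#' @param labels population labels, one per deme.
#' @param max_retries restarts of the sweep phase if the allele is lost.
#' @param seed master seed; identical seeds give bit-identical output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 3, deme_size = 500,
                       split_generations = c(0, 300, 600),
                       parent_deme = c(0, 1, 1),
                       migration_rate = 5e-4,
                       seq_length = 2e5, mu = 1e-6, rec_rate = 1.5e-6,
                       burn_in = 4 * deme_size,
                       sweep = NULL,
                       sample_sizes = rep(200, n_demes),
                       labels = paste0("pop", seq_len(n_demes)),
                       max_retries = 100, seed = 1) {
  stopifnot(n_demes >= 1, deme_size >= 2,
            length(split_generations) == n_demes,
            length(parent_deme) == n_demes,
            length(sample_sizes) == n_demes,
            length(labels) == n_demes)
  if (mu < 0 || rec_rate < 0 || migration_rate < 0)
    stop("rates must be >= 0")
  if (any(sample_sizes > 2 * deme_size))
    stop("sample_sizes must be <= 2 * deme_size haplotypes")
  if (any(sample_sizes %% 1 != 0))
    stop("sample_sizes must be integer haplotype counts")
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep),
              all(c("deme", "pos", "s", "onset") %in% names(sweep)))
    if (sweep$s < 0) stop("selection coefficient s must be >= 0")
    if (sweep$deme < 1 || sweep$deme > n_demes) stop("sweep deme out of range")
    if (sweep$pos < 1 || sweep$pos > seq_length) stop("focal position outside region")
  }
  structure(list(n_demes = as.integer(n_demes),
                 deme_size = as.integer(deme_size),
                 split_generations = as.integer(split_generations),
                 parent_deme = as.integer(parent_deme),
                 migration_rate = migration_rate,
                 seq_length = as.integer(seq_length),
                 mu = mu, rec_rate = rec_rate,
                 burn_in = as.integer(burn_in),
                 sweep = sweep,
                 sample_sizes = as.integer(sample_sizes),
                 labels = labels,
                 max_retries = as.integer(max_retries),
                 seed = seed),
            class = "sim_config")
}

#' Default sweep specification for the simulator
#' @param deme 1-based index of the deme under selection.
#' @param pos focal position in bp.
#' @param s selection coefficient (genic selection: fitness 1, 1+s, 1+2s).
#' @param onset generations before present at which the mutation arises.
#' @return list usable as the `sweep` slot of [sim_config()].
#' @export
sweep_spec <- function(deme = 1, pos = 1e5, s = 0.05, onset = 250) {
  list(deme = deme, pos = as.integer(pos), s = s, onset = as.integer(onset))
}

#' Run the forward Wright-Fisher simulation
#'
#' Returns phased, already-polarized haplotype matrices (ancestral state is
#' the founding population's allele, so a 1 is derived by construction) for
#' the pooled-sample polymorphic sites, plus a ground-truth table.
#'
#' @param config a [sim_config()].
#' @return list with `matrices` (named list of [haplo_matrix()]) and `truth`
#'   (list: per-site data.frame `sites` with a `selected` label, `focal_pos`,
#'   `sweep_deme`, per-deme `focal_freq` and `focal_freq_sample`, the sweep
#'   `trajectory` of per-generation focal frequencies, and `retries`).
#' @export
simulate_demes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sw <- config$sweep
  res <- .simulate_wf_cpp(
    config$n_demes, config$deme_size, config$split_generations,
    config$parent_deme - 1L, config$migration_rate, config$seq_length,
    config$mu, config$rec_rate, config$burn_in,
    !is.null(sw),
    if (is.null(sw)) 0L else as.integer(sw$deme - 1L),
    if (is.null(sw)) 0L else as.integer(sw$pos),
    if (is.null(sw)) 0 else sw$s,
    if (is.null(sw)) 0L else as.integer(sw$onset),
    config$max_retries, config$sample_sizes, as.numeric(config$seed))

  pos <- res$positions
  sites <- data.frame(chrom = rep("chr1", length(pos)), pos = pos,
                      ref = rep("A", length(pos)), alt = rep("G", length(pos)),
                      aa = rep("A", length(pos)), stringsAsFactors = FALSE)
  mats <- lapply(seq_len(config$n_demes), function(d) {
    haplo_matrix(res$matrices[[d]], sites,
                 sample_ids = sprintf("%s_%03d", config$labels[d],
                                      seq_len(config$sample_sizes[d] %/% 2L)),
                 pop = config$labels[d], polarized = TRUE)
  })
  names(mats) <- config$labels

  focal <- if (is.null(sw)) NA_integer_ else res$focal_pos
  selected <- if (is.null(sw)) rep(FALSE, length(pos)) else pos == focal
  truth <- list(
    sites = data.frame(chrom = sites$chrom, pos = pos, selected = selected,
                       stringsAsFactors = FALSE),
    focal_pos = focal,
    sweep_deme = if (is.null(sw)) NA_character_ else config$labels[sw$deme],
    focal_freq = stats::setNames(res$focal_freq, config$labels),
    focal_freq_sample = stats::setNames(res$focal_freq_sample, config$labels),
    trajectory = res$trajectory,
    retries = res$retries)
  list(matrices = mats, truth = truth)
}

#' Write simulated haplotypes as a phased VCF (and the truth table as TSV)
#'
#' Haplotype rows `2i-1, 2i` become the phased genotype of diploid sample
#' `i`. The ancestral allele is written to INFO/AA, so the file round-trips
#' through [read_phased_vcf()] + [polarize_by_ancestral()] bit-exactly.
#'
#' @param matrices named list of [haplo_matrix()] sharing one site list.
#' @param path output VCF path.
#' @param truth optional truth list from [simulate_demes()].
#' @param truth_path TSV path for the per-site truth labels.
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(matrices, path, truth = NULL, truth_path = NULL) {
  stopifnot(length(matrices) >= 1)
  m1 <- matrices[[1]]
  for (m in matrices) {
    check_shared_sites(m1, m)
    if (nrow(m$entries) %% 2L != 0L)
      stop("odd haplotype count in population ", m$pop,
           ": cannot pair into diploid samples")
  }
  s <- m1$sites
  sample_names <- unlist(lapply(matrices, function(m) {
    if (!is.null(m$sample_ids)) m$sample_ids
    else sprintf("%s_%03d", m$pop, seq_len(nrow(m$entries) %/% 2L))
  }))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  gt_block <- do.call(cbind, lapply(matrices, function(m) {
    e <- m$entries
    i1 <- seq(1L, nrow(e), by = 2L)
    gt <- matrix(paste0(e[i1, , drop = FALSE], "|",
                        e[i1 + 1L, , drop = FALSE]),
                 nrow = length(i1))
    t(gt)  # sites x samples
  }))
  aa <- ifelse(is.na(s$aa), ".", s$aa)
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                paste0("AA=", aa), "GT",
                apply(gt_block, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  if (!is.null(truth) && !is.null(truth_path)) {
    tt <- truth$sites
    tt$sweep_deme <- truth$sweep_deme
    utils::write.table(tt, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
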