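# Independent oracles and fixture builders shared across the test files.
# Oracles are deliberately written as direct, naive evaluations (all-pairs
# scans, literal formula transcriptions) independent of the package's
# implementation paths.

# random phased haplotype matrix fixture
rand_hm <- function(n_hap = 20, n_sites = 40, p = NULL, pop = "x",
                    max_pos = 50000) {
  if (is.null(p)) p <- runif(n_sites, 0.1, 0.9)
  E <- sapply(p, function(q) rbinom(n_hap, 1, q))
  # ensure positions strictly increasing
  pos <- sort(sample.int(max_pos, n_sites))
  haplo_matrix(E, data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                             stringsAsFactors = FALSE), pop = pop,
               polarized = TRUE)
}

# O(n^2) all-pairs shared-interval EHH: probability two random carriers are
# identical over the interval between core and j (core column excluded)
oracle_ehh_at <- function(E, core, j, carriers) {
  n <- length(carriers)
  if (j == core) return(1)
  rng <- if (j < core) j:(core - 1) else (core + 1):j
  same <- 0
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    if (all(E[carriers[a], rng] == E[carriers[b], rng])) same <- same + 1
  }
  same / choose(n, 2)
}

# full-arm oracle curve (stops after first below-cutoff point)
oracle_ehh_arm <- function(E, pos, core, carriers, cutoff, dir) {
  out <- data.frame(site = core, ehh = 1)
  j <- core + dir
  while (j >= 1 && j <= ncol(E)) {
    e <- oracle_ehh_at(E, core, j, carriers)
    out <- rbind(out, data.frame(site = j, ehh = e))
    if (e < cutoff) break
    j <- j + dir
  }
  out
}

# literal transcription of the Weir & Cockerham (1984) two-population
# estimator, written in the general r-population form with explicit sums
oracle_wc_fst <- function(geno1, geno2) {
  ns <- c(length(geno1), length(geno2))
  ps <- c(mean(geno1) / 2, mean(geno2) / 2)
  hs <- c(mean(geno1 == 1), mean(geno2 == 1))
  r <- 2
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  pbar <- sum(ns * ps) / sum(ns)
  s2 <- sum(ns * (ps - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ns * hs) / sum(ns)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# build a haplo_matrix pair from explicit genotype count tables
# counts: c(n_AA, n_Aa, n_aa) with "a" the derived allele
hm_from_geno_counts <- function(counts, pop = "x") {
  g <- rep(c(0L, 1L, 2L), counts)
  ent <- matrix(0L, nrow = 2 * length(g), ncol = 1)
  ent[2 * seq_along(g) - 1, 1] <- as.integer(g >= 1)
  ent[2 * seq_along(g), 1] <- as.integer(g == 2)
  haplo_matrix(ent, data.frame(chrom = "chr1", pos = 100L, ref = "A",
                               alt = "G", stringsAsFactors = FALSE),
               pop = pop, polarized = TRUE)
}

# study-conditions exon model (package canonical tiling)
study_exons <- function() study_exon_model()

# --- cached replicate study -------------------------------------------------
# One set of sweep/neutral replicate pipelines is shared by the synthetic-
# data invariants and the sweep-recovery acceptance test so the expensive
# simulations run once per session.
.replicate_cache <- new.env(parent = emptyenv())

replicate_study <- function(n_sweep = 50, n_neutral = 50) {
  key <- paste0("s", n_sweep, "_n", n_neutral)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  ex <- study_exons()
  cfg <- scan_config(outgroup = "pop3")
  summarize <- function(seed, sweep) {
    sim <- simulate_study(seed, sweep = sweep)
    res <- suppressWarnings(run_scan_pipeline(sim$matrices, ex, cfg))
    focal <- if (sweep) sim$focal_pos else 1e5
    near <- res$sites$chrom == "chr1" & abs(res$sites$pos - focal) <= 1e4
    called <- res$candidates[res$candidates$final_call, , drop = FALSE]
    mean_abs <- function(tr) {
      z <- tr$standardized[near]
      if (all(is.na(z))) NA_real_ else mean(abs(z), na.rm = TRUE)
    }
    cand <- res$candidates
    data.frame(
      seed = seed, sweep = sweep,
      called_near_focal = any(called$population == "pop1" &
                                called$chrom == "chr1" &
                                abs(called$pos - focal) <= 1e4),
      ihs_focal_pop1 = mean_abs(res$tracks$pop1),
      ihs_focal_pop3 = mean_abs(res$tracks$pop3),
      xpehh12_focal = mean(res$tracks$xpehh_pop1_vs_pop2$raw[near],
                           na.rm = TRUE),
      invariant_ok = !any(cand$final_call &
                            !((cand$ihs_hit | cand$xpehh_hit) &
                                cand$fst_high & cand$exonic)))
  }
  sweep_df <- do.call(rbind, lapply(seq_len(n_sweep), summarize, sweep = TRUE))
  neut_df <- do.call(rbind, lapply(100 + seq_len(n_neutral), summarize,
                                   sweep = FALSE))
  out <- list(sweep = sweep_df, neutral = neut_df)
  .replicate_cache[[key]] <- out
  out
}
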