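write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  writeLines(c(header, lines), path)
  path
}

two_sample_panel <- data.frame(sample = c("s1", "s2"),
                               population = c("P", "P"),
                               stringsAsFactors = FALSE)

test_that("read_phased_vcf keeps biallelic SNPs and drops indels", {
  p <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\t.\tA\tAT\t.\tPASS\tAA=A\tGT\t0|0\t0|1",   # indel
    "chr1\t300\t.\tC\tT\t.\tPASS\tAA=T\tGT\t0|0\t1|0",
    "chr1\t350\t.\tC\tT,G\t.\tPASS\tAA=C\tGT\t0|0\t0|2",  # multi-allelic
    "chr1\t400\t.\tG\tA\t.\tPASS\tAA=G\tGT\t1|1\t0|0"))
  mats <- read_phased_vcf(p, two_sample_panel)
  m <- mats$P
  expect_equal(dim(m), c(4L, 3L))
  expect_equal(m$sites$pos, c(100L, 300L, 400L))
  # "0|1" at pos 100 for s1: exactly one derived among s1's two rows
  expect_equal(sum(m$entries[1:2, 1]), 1L)
  # pos 400: s1 = 1|1, s2 = 0|0
  expect_equal(m$entries[, 3], c(1L, 1L, 0L, 0L))
})

test_that("read_phased_vcf rejects unphased genotypes naming the offender", {
  p <- write_vcf_fixture(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "chr1\t200\t.\tC\tT\t.\tPASS\tAA=C\tGT\t0/1\t0|0"))
  expect_error(read_phased_vcf(p, two_sample_panel), "unphased.*200.*s1")
})

test_that("read_phased_vcf errors when a panel sample is absent", {
  p <- write_vcf_fixture("chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1")
  bad <- data.frame(sample = c("s1", "s9"), population = c("P", "P"))
  expect_error(read_phased_vcf(p, bad), "s9")
})

test_that("polarization flips alt-ancestral columns and filters bad AA", {
  set.seed(7)
  n <- 10
  ent <- matrix(rbinom(n * 10, 1, 0.5), n, 10)
  sites <- data.frame(chrom = "chr1", pos = seq(100, 1000, by = 100),
                      ref = rep("A", 10), alt = rep("G", 10),
                      aa = c("A", "G", "A", NA, "G", "C", "a", "A", NA, "G"),
                      stringsAsFactors = FALSE)
  m <- haplo_matrix(ent, sites, pop = "P")
  pol <- polarize_by_ancestral(m)
  rep_ <- attr(pol, "polarize_report")
  # kept: AA in {ref, alt} and high confidence -> sites 1,2,3,5,8,10
  expect_equal(n_sites(pol), 6L)
  expect_equal(rep_$n_missing_aa, 2L)
  expect_equal(rep_$n_mismatch, 1L)
  expect_equal(rep_$n_low_confidence, 1L)
  # ancestral = ref: column unchanged; ancestral = alt: bits flipped
  expect_equal(pol$entries[, 1], ent[, 1])
  expect_equal(pol$entries[, 2], 1L - ent[, 2])
  # lowercase accepted when requested
  pol2 <- polarize_by_ancestral(m, low_confidence = "use")
  expect_equal(n_sites(pol2), 7L)
})

test_that("MAF filter is inclusive at the boundary and matches recount", {
  # 100 haplotypes: 4 derived copies (0.04) dropped, 5 copies (0.05) kept
  ent <- cbind(c(rep(1L, 4), rep(0L, 96)), c(rep(1L, 5), rep(0L, 95)))
  m <- haplo_matrix(ent, data.frame(chrom = "chr1", pos = c(10L, 20L),
                                    ref = "A", alt = "G"), pop = "P",
                    polarized = TRUE)
  f <- filter_maf(m, 0.05)
  expect_equal(n_sites(f), 1L)
  expect_equal(f$sites$pos, 20L)

  set.seed(11)
  big <- rand_hm(n_hap = 40, n_sites = 500,
                 p = runif(500, 0.01, 0.99), max_pos = 1e6)
  fb <- filter_maf(big, 0.05)
  cnt <- colSums(big$entries)
  keep <- pmin(cnt, 40 - cnt) / 40 >= 0.05   # brute-force recount
  expect_equal(fb$sites$pos, big$sites$pos[keep])
  # idempotence
  expect_identical(filter_maf(fb, 0.05)$entries, fb$entries)
  expect_error(filter_maf(big, 0.7), "maf_min")
  expect_error(filter_maf(big, -0.1), "maf_min")
})

test_that("region annotation respects BED half-open coordinates", {
  # BED [100, 101) covers exactly the 0-based base 100 = 1-based pos 101
  rs <- region_set(data.frame(chrom = "chr1", start = 100, end = 101))
  expect_true(annotate_regions(data.frame(chrom = "chr1", pos = 101L), rs))
  expect_false(annotate_regions(data.frame(chrom = "chr1", pos = 100L), rs))
  expect_false(annotate_regions(data.frame(chrom = "chr1", pos = 102L), rs))
  rs2 <- region_set(data.frame(chrom = "chr1", start = 100, end = 102))
  expect_true(annotate_regions(data.frame(chrom = "chr1", pos = 101L), rs2))

  # brute-force containment scan on random sites and intervals
  set.seed(3)
  sites <- data.frame(chrom = "chr1", pos = sort(sample.int(50000, 1000)))
  iv <- data.frame(chrom = "chr1",
                   start = st <- sample.int(49000, 50),
                   end = st + sample.int(800, 50))
  rs3 <- region_set(iv)
  got <- annotate_regions(sites, rs3)
  want <- vapply(sites$pos - 1L, function(p0)
    any(p0 >= iv$start & p0 < iv$end), logical(1))
  expect_equal(got, want)

  # absent chromosome: all false, logged not fatal
  s2 <- data.frame(chrom = "chr9", pos = c(150L, 250L))
  expect_message(f <- annotate_regions(s2, rs3), "chr9")
  expect_equal(f, c(FALSE, FALSE))
})

test_that("region sets merge overlapping intervals and reject start >= end", {
  rs <- region_set(data.frame(chrom = "chr1",
                              start = c(10, 50, 40), end = c(30, 80, 60)))
  expect_equal(nrow(rs$intervals), 2L)
  expect_equal(rs$intervals$end[2], 80)
  expect_error(region_set(data.frame(chrom = "c", start = 5, end = 5)))
})

test_that("emit_vcf round-trips through read_phased_vcf exactly", {
  sim <- simulate_demes(sim_config(n_demes = 2,
                                   split_generations = c(0, 40),
                                   parent_deme = c(0, 1), deme_size = 60,
                                   burn_in = 240, seq_length = 2e4,
                                   sample_sizes = c(20, 16),
                                   labels = c("AF", "EU"), seed = 5))
  vcf <- tempfile(fileext = ".vcf")
  truth_tsv <- tempfile(fileext = ".tsv")
  emit_vcf(sim$matrices, vcf, truth = sim$truth, truth_path = truth_tsv)
  panel <- data.frame(
    sample = unlist(lapply(sim$matrices, `[[`, "sample_ids")),
    population = rep(c("AF", "EU"), c(10, 8)))
  back <- read_phased_vcf(vcf, panel, c("AF", "EU"))
  for (p in c("AF", "EU")) {
    pol <- polarize_by_ancestral(back[[p]])
    expect_identical(pol$entries, sim$matrices[[p]]$entries)
    expect_identical(pol$sites$pos, sim$matrices[[p]]$sites$pos)
  }
  tt <- read.table(truth_tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(tt), n_sites(sim$matrices$AF))
})

test_that("sample order in the panel does not change per-site statistics", {
  set.seed(21)
  m <- rand_hm(n_hap = 24, n_sites = 60)
  perm <- sample(24)
  m2 <- haplo_matrix(m$entries[perm, ], m$sites[, 1:5], pop = m$pop,
                     polarized = TRUE)
  t1 <- ihs_scan(m, max_gap = 0)
  t2 <- ihs_scan(m2, max_gap = 0)
  expect_equal(t1$raw, t2$raw)
  expect_equal(t1$reason, t2$reason)
})
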