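std_track <- function(z, pos = seq_along(z) * 100L, chrom = "chr1") {
  tr <- new_score_track(
    data.frame(chrom = chrom, pos = as.integer(pos),
               derived_freq = rep(0.5, length(z)), maf = rep(0.5, length(z))),
    raw = z, reason = rep("ok", length(z)), statistic = "ihs", pops = "x")
  tr$standardized <- z
  tr
}

test_that("window counts match a brute-force recount", {
  z <- rep(0, 60)
  z[26:35] <- 3           # exactly the middle 10 exceed
  tr <- std_track(z)
  w <- window_counts(tr, window_size = 51, score_cutoff = 2)
  expect_equal(nrow(w), 10L)
  brute <- vapply(seq_len(10), function(f) sum(abs(z[f:(f + 50)]) > 2),
                  numeric(1))
  expect_equal(w$count, as.integer(brute))
  expect_false(any(w$truncated))
  # counts are invariant to the sign of the scores
  w2 <- window_counts(std_track(-z), 51, 2)
  expect_equal(w2$count, w$count)
  # all small scores: every count zero
  w3 <- window_counts(std_track(rep(1.5, 60)), 51, 2)
  expect_true(all(w3$count == 0))
  # short chromosome: one truncated window
  w4 <- window_counts(std_track(c(3, 0, 3)), 51, 2)
  expect_equal(nrow(w4), 1L)
  expect_true(w4$truncated)
  expect_equal(w4$count, 2L)
  expect_error(window_counts(tr, window_size = 50), "odd")
})

test_that("top-window qualification follows the strict top-quantile rule", {
  w <- data.frame(chrom = "chr1", first = 1:1000, last = 51:1050,
                  start_pos = 1:1000, end_pos = 2:1001, span = 1L,
                  count = sample(1000), truncated = FALSE)
  attr(w, "scored_rows") <- list(chr1 = 1:1050)
  f <- top_window_flags(w, quantile = 0.01)
  expect_equal(sum(f$qualify), 10L)
  # duplicating every window leaves the count threshold unchanged
  w2 <- rbind(w, w)
  attr(w2, "scored_rows") <- attr(w, "scored_rows")
  f2 <- top_window_flags(w2, quantile = 0.01)
  expect_equal(attr(f2, "threshold"), attr(f, "threshold"))
  # degenerate distribution: warning, nothing qualifies
  w$count <- 0L
  expect_warning(f3 <- top_window_flags(w, 0.01), "degenerate")
  expect_equal(sum(f3$qualify), 0L)
})

test_that("haplotype hits require both exceedance and a qualifying window", {
  set.seed(14)
  z <- rnorm(200)
  z[c(40:44, 120:129)] <- 4 * sign(rnorm(15))
  tr <- std_track(z)
  w <- window_counts(tr, window_size = 11, score_cutoff = 2)
  w <- top_window_flags(w, quantile = 0.05)
  hits <- haplotype_hits(tr, w, score_cutoff = 2)
  # brute-force double loop
  qual <- which(w$qualify)
  want <- vapply(seq_len(200), function(i) {
    abs(z[i]) > 2 && any(i >= w$first[qual] & i <= w$last[qual])
  }, logical(1))
  expect_equal(hits, want)
  # an exceeding SNP outside all qualifying windows is not a hit
  outside <- which(abs(z) > 2 & !want)
  if (length(outside) > 0) expect_false(any(hits[outside]))
  # a non-exceeding SNP inside a qualifying window is not a hit
  inside_small <- which(abs(z) <= 2 &
                          vapply(seq_len(200), function(i)
                            any(i >= w$first[qual] & i <= w$last[qual]),
                            logical(1)))
  expect_false(any(hits[inside_small]))
})

test_that("the intersection decision rule is applied per population", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                      ref = "A", alt = "G")
  ihs <- list(P1 = c(TRUE, TRUE, FALSE, FALSE))
  xp <- list(list(pops = c("P1", "P2"),
                  hits = c(FALSE, FALSE, TRUE, TRUE),
                  score = c(0, 0, 2.5, -2.5)))
  fst <- list(list(pops = c("P1", "P2"),
                   flags = c(TRUE, TRUE, TRUE, TRUE)))
  exonic <- c(TRUE, FALSE, TRUE, TRUE)
  cand <- decide(sites, ihs, xp, fst, NULL, exonic)
  p1 <- cand[cand$population == "P1", ]
  # site 10: ihs hit + fst + exonic -> called
  expect_true(p1$final_call[p1$pos == 10])
  # site 20: ihs hit + fst but not exonic -> not called
  expect_false(p1$final_call[p1$pos == 20])
  # site 30: xpehh hit attributed to P1 (positive score)
  expect_true(p1$final_call[p1$pos == 30])
  # site 40: negative score attributes the hit to P2
  expect_false(40 %in% p1$pos && p1$xpehh_hit[p1$pos == 40])
  p2 <- cand[cand$population == "P2", ]
  expect_true(p2$final_call[p2$pos == 40])
  # the final_call implication invariant holds on every row
  expect_true(all(!cand$final_call |
                    ((cand$ihs_hit | cand$xpehh_hit) & cand$fst_high &
                       cand$exonic)))
})

test_that("PBS is corroborative by default and gating in strict mode", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "G")
  ihs <- list(P1 = c(TRUE, TRUE))
  fst <- list(list(pops = c("P1", "P2"), flags = c(TRUE, TRUE)))
  pbs_rec <- list(P1 = list(pbs = c(1.5, 0.1), high = c(TRUE, FALSE)))
  cand <- decide(sites, ihs, list(), fst, pbs_rec, c(TRUE, TRUE))
  expect_true(all(cand$final_call))        # discordant PBS flagged, not vetoed
  expect_equal(cand$pbs_high, c(TRUE, FALSE))
  strict <- decide(sites, ihs, list(), fst, pbs_rec, c(TRUE, TRUE),
                   pbs_strict = TRUE)
  expect_equal(strict$final_call, c(TRUE, FALSE))
})

test_that("fst corroboration breadth k is honoured", {
  sites <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G")
  ihs <- list(P1 = TRUE)
  fst <- list(list(pops = c("P1", "P2"), flags = TRUE),
              list(pops = c("P1", "P3"), flags = FALSE))
  c1 <- decide(sites, ihs, list(), fst, NULL, TRUE, fst_k = 1)
  expect_true(c1$final_call)
  c2 <- decide(sites, ihs, list(), fst, NULL, TRUE, fst_k = Inf)
  expect_false(c2$final_call)
})

test_that("annotation join keeps unmatched candidates and duplicates keys", {
  sites <- data.frame(chrom = "chr1", pos = seq(10L, 100L, 10L),
                      ref = "A", alt = "G")
  ihs <- list(P1 = rep(TRUE, 10))
  fst <- list(list(pops = c("P1", "P2"), flags = rep(TRUE, 10)))
  cand <- decide(sites, ihs, list(), fst, NULL, rep(TRUE, 10))
  # empty table: annotations empty, candidate set unchanged
  a0 <- annotate_candidates(cand, NULL)
  expect_equal(nrow(a0), 10L)
  expect_true(all(a0$gene == ""))
  # 3 of 10 annotated
  assoc <- data.frame(chrom = "chr1", pos = c(10L, 40L, 90L), ref = "A",
                      alt = "G", gene = c("G1", "G2", "G3"),
                      cancer_types = c("THCA", "THCA,BRCA", "AML"))
  a3 <- annotate_candidates(cand, assoc)
  expect_equal(sum(nzchar(a3$gene)), 3L)
  expect_equal(a3$gene[a3$pos == 40], "G2")
  # duplicate keys: all kept, with a warning
  assoc2 <- rbind(assoc, assoc[1, ])
  expect_warning(a4 <- annotate_candidates(cand, assoc2), "duplicate")
  expect_equal(nrow(a4), 11L)
})

test_that("stricter thresholds never add candidates", {
  sim <- simulate_demes(sim_config(seed = 77, sweep = sweep_spec(onset = 200)))
  ex <- study_exons()
  loose <- suppressWarnings(run_scan_pipeline(
    sim$matrices, ex, scan_config(outgroup = "pop3", window_quantile = 0.2)))
  strict <- suppressWarnings(run_scan_pipeline(
    sim$matrices, ex, scan_config(outgroup = "pop3", window_quantile = 0.01)))
  key <- function(d) paste(d$pos, d$population)
  called_loose <- key(loose$candidates[loose$candidates$final_call, ])
  called_strict <- key(strict$candidates[strict$candidates$final_call, ])
  expect_true(all(called_strict %in% called_loose))
})
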