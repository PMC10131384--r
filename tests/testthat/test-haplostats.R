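make_hm <- function(E, pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(E)) * 100L
  haplo_matrix(E, data.frame(chrom = "chr1", pos = as.integer(pos),
                             ref = "A", alt = "G", stringsAsFactors = FALSE),
               pop = "x", polarized = TRUE)
}

test_that("EHH is 1 everywhere for identical carrier haplotypes", {
  E <- matrix(0L, nrow = 4, ncol = 9)
  E[, 5] <- 1L                      # shared derived core
  m <- make_hm(E)
  cv <- ehh(m, 5, "derived", cutoff = 0.05)
  expect_true(all(cv$arms$ehh == 1))
  expect_true(all(cv$edge))         # never decayed below cutoff
})

test_that("EHH matches the combinatorial example with groups {3,2,1}", {
  # 6 derived carriers whose sub-haplotypes over sites 2..3 split into
  # groups of 3 ((0,0)), 2 ((1,0)) and 1 ((0,1)):
  # EHH = (C(3,2)+C(2,2))/C(6,2) = 4/15
  E <- cbind(rep(1L, 6),
             c(0L, 0L, 0L, 1L, 1L, 0L),
             c(0L, 0L, 0L, 0L, 0L, 1L))
  m <- make_hm(E)
  cv <- ehh(m, 1, "derived", cutoff = 0)
  right <- cv$arms[cv$arms$side == "right", ]
  expect_equal(right$ehh[right$site == 3], 4 / 15)
})

test_that("EHH equals the all-pairs oracle and is monotone in [0,1]", {
  set.seed(42)
  for (rep in 1:15) {
    m <- rand_hm(n_hap = sample(8:24, 1), n_sites = sample(20:50, 1))
    core <- sample(2:(n_sites(m) - 1), 1)
    for (al in c("derived", "ancestral", "pooled")) {
      carriers <- switch(al, derived = which(m$entries[, core] == 1),
                         ancestral = which(m$entries[, core] == 0),
                         pooled = seq_len(n_haplotypes(m)))
      if (length(carriers) < 2) next
      cv <- ehh(m, core, al, cutoff = 0.05)
      for (side in c("left", "right")) {
        got <- cv$arms[cv$arms$side == side, ]
        if (side == "left") got <- got[rev(seq_len(nrow(got))), ]
        dir <- if (side == "left") -1 else 1
        want <- oracle_ehh_arm(m$entries, m$sites$pos, core, carriers,
                               0.05, dir)
        expect_equal(got$site, want$site)
        expect_equal(got$ehh, want$ehh, tolerance = 1e-12)
        expect_true(all(got$ehh >= 0 & got$ehh <= 1))
        expect_true(all(diff(want$ehh) <= 1e-12))   # monotone non-increasing
      }
    }
  }
})

test_that("monomorphic cores are rejected", {
  E <- matrix(0L, 4, 5); E[1, 3] <- 1L
  m <- make_hm(E)
  expect_error(ehh(m, 3, "derived"), "monomorphic core")
})

# left rows ascend towards the core (core last); right rows start at the core
manual_curve <- function(left, right, cutoff = 0.05,
                         edge = c(left = FALSE, right = FALSE)) {
  arms <- rbind(
    data.frame(side = "left", site = seq_len(nrow(left)),
               ehh = left$ehh, pos = left$pos),
    data.frame(side = "right", site = nrow(left) - 1 + seq_len(nrow(right)),
               ehh = right$ehh, pos = right$pos))
  structure(list(core = nrow(left), allele = "derived",
                 n_carriers = 10, cutoff = cutoff, arms = arms,
                 edge = edge, gap = c(left = FALSE, right = FALSE)),
            class = "ehh_curve")
}

test_that("iHH integrates the printed worked examples", {
  # EHH == 1 over 1000 bp on both arms: area = 2 * 1000
  flat <- data.frame(pos = c(0, 500, 1000), ehh = 1)
  core_pt <- data.frame(pos = 0, ehh = 1)
  cv <- manual_curve(left = data.frame(pos = c(-1000, -500, 0), ehh = 1),
                     right = flat)
  expect_equal(ihh(cv), 2000)

  # one arm (0,1.0) (100,0.5) (200,0.04), cutoff 0.05: only trapezoid 0-100
  # contributes, area 75; the 0.04 endpoint is excluded
  cv2 <- manual_curve(left = core_pt,
                      right = data.frame(pos = c(0, 100, 200),
                                         ehh = c(1, 0.5, 0.04)))
  expect_equal(ihh(cv2), 75)

  # doubling all inter-site distances doubles the area
  cv3 <- manual_curve(left = core_pt,
                      right = data.frame(pos = c(0, 200, 400),
                                         ehh = c(1, 0.5, 0.04)))
  expect_equal(ihh(cv3), 2 * ihh(cv2))

  # edge-truncated curves are suppressed with a reason
  cv4 <- manual_curve(left = core_pt, right = flat,
                      edge = c(left = FALSE, right = TRUE))
  expect_true(is.na(ihh(cv4)))
  expect_equal(attr(ihh(cv4), "reason"), "edge")
})

test_that("iHS is antisymmetric under allele-label swap and zero for mirrors", {
  set.seed(8)
  m <- rand_hm(n_hap = 30, n_sites = 41, p = runif(41, 0.3, 0.7))
  t1 <- ihs_scan(m, max_gap = 0)
  m_flipped <- make_hm(1L - m$entries, m$sites$pos)
  t2 <- ihs_scan(m_flipped, max_gap = 0)
  ok <- t1$reason == "ok" & t2$reason == "ok"
  expect_gt(sum(ok), 0)
  expect_equal(t1$raw[ok], -t2$raw[ok], tolerance = 1e-12)

  # ancestral and derived carriers with mirror-image haplotype structure
  # around a centred core (positions equally spaced): iHS must be exactly 0
  set.seed(5)
  A <- matrix(rbinom(8 * 12, 1, 0.5), nrow = 8, ncol = 12)
  D <- A[, 12:1]
  E <- rbind(cbind(A[, 1:6], 0L, A[, 7:12]),
             cbind(D[, 1:6], 1L, D[, 7:12]))
  storage.mode(E) <- "integer"
  m3 <- make_hm(E)
  t3 <- ihs_scan(m3, cutoff = 0.05, max_gap = 0, min_carriers = 2)
  expect_equal(t3$reason[7], "ok")
  expect_equal(t3$raw[7], 0, tolerance = 1e-12)
})

test_that("iHS equals an independent R-level composition of oracle EHH", {
  set.seed(13)
  m <- rand_hm(n_hap = 16, n_sites = 30, p = runif(30, 0.25, 0.75))
  tr <- ihs_scan(m, cutoff = 0.05, max_gap = 0)
  for (core in which(tr$reason == "ok")) {
    areas <- vapply(0:1, function(allele) {
      carriers <- which(m$entries[, core] == allele)
      a <- 0
      for (dir in c(-1, 1)) {
        arm <- oracle_ehh_arm(m$entries, m$sites$pos, core, carriers,
                              0.05, dir)
        for (k in seq_len(nrow(arm) - 1)) {
          if (arm$ehh[k] < 0.05 || arm$ehh[k + 1] < 0.05) break
          a <- a + 0.5 * (arm$ehh[k] + arm$ehh[k + 1]) *
            abs(m$sites$pos[arm$site[k + 1]] - m$sites$pos[arm$site[k]])
        }
      }
      a
    }, numeric(1))
    expect_equal(tr$raw[core], log(areas[1] / areas[2]), tolerance = 1e-9)
  }
})

test_that("xpEHH is zero for identical populations and antisymmetric", {
  set.seed(9)
  m <- rand_hm(n_hap = 20, n_sites = 35)
  m2 <- haplo_matrix(m$entries, m$sites[, 1:5], pop = "y", polarized = TRUE)
  t0 <- xpehh_scan(m, m2, max_gap = 0, pooled_maf_min = 0)
  expect_true(all(abs(t0$raw[t0$reason == "ok"]) < 1e-12))

  mb <- rand_hm(n_hap = 16, n_sites = 35, pop = "y")
  mb <- haplo_matrix(mb$entries, m$sites[, 1:5], pop = "y", polarized = TRUE)
  tab <- xpehh_scan(m, mb, max_gap = 0, pooled_maf_min = 0)
  tba <- xpehh_scan(mb, m, max_gap = 0, pooled_maf_min = 0)
  ok <- tab$reason == "ok" & tba$reason == "ok"
  expect_gt(sum(ok), 0)
  expect_equal(tab$raw[ok], -tba$raw[ok], tolerance = 1e-12)
})

test_that("a sweep in one deme drives positive focal xpEHH against the other", {
  study <- replicate_study()
  expect_gte(mean(study$sweep$xpehh12_focal > 0, na.rm = TRUE), 0.8)
})

test_that("standardization satisfies the exact per-bin identities", {
  # single bin with raw {-1, +1}: population moments keep the values
  tr <- new_score_track(
    data.frame(chrom = "chr1", pos = c(10L, 20L), derived_freq = c(.4, .6),
               maf = c(.4, .4)), raw = c(-1, 1), reason = c("ok", "ok"),
    statistic = "ihs", pops = "x")
  std <- standardize(tr, n_bins = 1, min_bin_size = 1)
  expect_equal(std$standardized, c(-1, 1))

  set.seed(10)
  n <- 5000
  f <- runif(n)
  raw <- rnorm(n, mean = 2 * f, sd = 0.5 + f)
  tr2 <- new_score_track(
    data.frame(chrom = "chr1", pos = seq_len(n) * 10L, derived_freq = f,
               maf = pmin(f, 1 - f)), raw = raw, reason = rep("ok", n),
    statistic = "ihs", pops = "x")
  std2 <- standardize(tr2, n_bins = 20)
  bins <- attr(std2, "bins")
  expect_true(all(bins$n >= 20))
  width <- 1 / 20
  bin_of <- pmin(pmax(ceiling(f / width), 1), 20)
  # reconstruct merged-bin membership from reported bounds
  for (b in seq_len(nrow(bins))) {
    inb <- f > bins$lower[b] & f <= bins$upper[b] &
      !is.na(std2$standardized)
    z <- std2$standardized[inb]
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(mean(z^2) - 1), 1e-6)
  }
})

test_that("zero-variance bins are set undefined", {
  tr <- new_score_track(
    data.frame(chrom = "chr1", pos = 1:25 * 10L, derived_freq = rep(.5, 25),
               maf = rep(.5, 25)), raw = rep(3, 25), reason = rep("ok", 25),
    statistic = "ihs", pops = "x")
  std <- standardize(tr, n_bins = 1)
  expect_true(all(is.na(std$standardized)))
  expect_true(all(std$reason == "constant_bin"))
})

test_that("neutral standardized scores put ~4.6% of mass beyond |2|", {
  set.seed(2024)
  n <- 10000
  f <- runif(n)
  raw <- rnorm(n, mean = sin(6 * f), sd = 0.3 + 2 * f)  # bin-varying moments
  tr <- new_score_track(
    data.frame(chrom = "chr1", pos = seq_len(n) * 5L, derived_freq = f,
               maf = pmin(f, 1 - f)), raw = raw, reason = rep("ok", n),
    statistic = "ihs", pops = "x")
  std <- standardize(tr, n_bins = 100)
  tail_mass <- mean(abs(std$standardized) > 2, na.rm = TRUE)
  expect_lt(abs(tail_mass - 0.046), 0.01)
})
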