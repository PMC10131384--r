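#' Read a sample-to-population panel table
#'
#' Two-column TSV (`sample`, `population`), with or without a header line.
#'
#' @param path TSV file path.
#' @return data.frame with columns `sample` and `population`.
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("panel must have two columns: sample, population")
  if (identical(tolower(df[1, 1]), "sample")) df <- df[-1, , drop = FALSE]
  data.frame(sample = as.character(df[[1]]),
             population = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Region set from BED3 intervals
#'
#' Intervals are 0-based half-open as in BED. Overlapping or touching
#' intervals are merged and the set is sorted; these invariants are what
#' [annotate_regions()] relies on.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`.
#' @param label free-text label (e.g. "exons").
#' @return object of class `region_set`.
#' @export
region_set <- function(intervals, label = "regions") {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("region intervals must satisfy start < end (0-based half-open)")
  merged <- do.call(rbind, lapply(split(intervals, intervals$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    out <- list()
    cs <- d$start[1]; ce <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= ce) ce <- max(ce, d$end[i])
      else { out[[length(out) + 1L]] <- c(cs, ce); cs <- d$start[i]; ce <- d$end[i] }
    }
    out[[length(out) + 1L]] <- c(cs, ce)
    m <- do.call(rbind, out)
    data.frame(chrom = d$chrom[1], start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  structure(list(intervals = merged, label = label), class = "region_set")
}

#' Read a BED3 file into a region set
#' @param path BED file (chrom, start, end; tab separated, no header).
#' @param label label for the set.
#' @return a [region_set()].
#' @export
read_bed <- function(path, label = "regions") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  region_set(data.frame(chrom = as.character(df[[1]]),
                        start = as.integer(df[[2]]),
                        end = as.integer(df[[3]]),
                        stringsAsFactors = FALSE), label = label)
}

#' Read phased diploid genotypes from a VCF into per-population matrices
#'
#' Parses a VCF 4.x file (via the vcfR package), drops indels, multi-allelic
#' records and sites with any missing genotype, requires every genotype to be
#' phased, and splits samples by population. Entries are REF/ALT coded
#' (0 = REF); run [polarize_by_ancestral()] to obtain ancestral/derived
#' coding from the INFO/AA annotation.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param panel data.frame from [read_panel()].
#' @param populations which populations to load; default all in the panel.
#' @return named list of [haplo_matrix()] objects sharing one site list.
#' @export
read_phased_vcf <- function(vcf_path, panel, populations = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(populations)) populations <- unique(panel$population)
  panel <- panel[panel$population %in% populations, , drop = FALSE]
  missing_samples <- setdiff(panel$sample, colnames(gt))
  if (length(missing_samples) > 0)
    stop("panel sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))

  aa <- vcfR::extract.info(vcf, "AA")
  if (is.null(aa)) aa <- rep(NA_character_, nrow(fix))

  # biallelic SNPs only: indels and multi-allelic records are removed
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T", "a", "c", "g", "t") &
    fix$ALT %in% c("A", "C", "G", "T", "a", "c", "g", "t")

  gt <- gt[, panel$sample, drop = FALSE]
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  bad_unphased <- unphased & keep
  if (any(bad_unphased)) {
    w <- which(bad_unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at %s:%s for sample %s",
                 fix$CHROM[w[1]], fix$POS[w[1]], panel$sample[w[2]]))
  }
  # missing-genotype sites are dropped before analysis
  miss <- is.na(gt) |
    matrix(gt %in% c(".|.", ".", ".|0", "0|.", ".|1", "1|."),
           nrow = nrow(gt))
  keep <- keep & rowSums(miss) == 0
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  aa <- aa[keep]

  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  if (any(a1 %in% c("2", "3") | a2 %in% c("2", "3")))
    stop("unexpected multi-allelic genotype after filtering")

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, aa = aa,
                      stringsAsFactors = FALSE)
  out <- lapply(populations, function(p) {
    ids <- panel$sample[panel$population == p]
    n <- length(ids)
    ent <- matrix(0L, nrow = 2L * n, ncol = nrow(sites))
    for (i in seq_len(n)) {
      ent[2L * i - 1L, ] <- as.integer(a1[, ids[i]])
      ent[2L * i, ] <- as.integer(a2[, ids[i]])
    }
    haplo_matrix(ent, sites, sample_ids = ids, pop = p)
  })
  names(out) <- populations
  out
}

#' Polarize a haplotype matrix by its ancestral-allele annotation
#'
#' Recodes entries so that 1 means the derived (non-ancestral) allele. Sites
#' whose ancestral allele is missing, low-confidence (lowercase, following
#' 1000 Genomes annotation practice) or equal to neither REF nor ALT are
#' excluded; the counts are attached as the `"polarize_report"` attribute.
#'
#' @param m a [haplo_matrix()].
#' @param low_confidence `"exclude"` (default) drops lowercase AA calls;
#'   `"use"` accepts them (case-insensitively).
#' @return polarized `haplo_matrix` (possibly with fewer sites).
#' @export
polarize_by_ancestral <- function(m, low_confidence = c("exclude", "use")) {
  low_confidence <- match.arg(low_confidence)
  s <- m$sites
  aa <- as.character(s$aa)
  aa[aa %in% c("", ".", "-", "N", "n")] <- NA_character_
  lowconf <- !is.na(aa) & aa %in% c("a", "c", "g", "t")
  if (low_confidence == "use") aa <- toupper(aa)
  is_ref <- !is.na(aa) & aa == s$ref
  is_alt <- !is.na(aa) & aa == s$alt
  mismatch <- !is.na(aa) & aa %in% c("A", "C", "G", "T") & !is_ref & !is_alt
  keep <- is_ref | is_alt
  report <- list(n_in = nrow(s), n_kept = sum(keep),
                 n_missing_aa = sum(is.na(aa)),
                 n_low_confidence = if (low_confidence == "exclude")
                   sum(lowconf) else 0L,
                 n_mismatch = sum(mismatch))
  ent <- m$entries[, keep, drop = FALSE]
  flip <- is_alt[keep]
  if (any(flip)) ent[, flip] <- 1L - ent[, flip]
  s <- s[keep, , drop = FALSE]
  # after polarization REF/ALT are reported as ancestral/derived alleles
  new_ref <- ifelse(flip, s$alt, s$ref)
  new_alt <- ifelse(flip, s$ref, s$alt)
  s$ref <- new_ref
  s$alt <- new_alt
  s$aa <- toupper(as.character(s$aa))
  out <- haplo_matrix(ent, s[, c("chrom", "pos", "ref", "alt", "aa")],
                      sample_ids = m$sample_ids, pop = m$pop, polarized = TRUE)
  attr(out, "polarize_report") <- report
  out
}

#' Filter sites by within-population minor allele frequency
#'
#' Retains exactly the sites with `min(f, 1 - f) >= maf_min`, where `f` is the
#' derived-allele frequency in this matrix. The bound is inclusive.
#'
#' @param m polarized [haplo_matrix()].
#' @param maf_min MAF threshold in `[0, 0.5]`.
#' @return filtered `haplo_matrix`.
#' @export
filter_maf <- function(m, maf_min = 0.05) {
  if (!is.numeric(maf_min) || length(maf_min) != 1 ||
      maf_min < 0 || maf_min > 0.5)
    stop("maf_min must be a single value in [0, 0.5]")
  keep <- m$sites$maf >= maf_min
  out <- haplo_matrix(m$entries[, keep, drop = FALSE],
                      m$sites[keep, c("chrom", "pos", "ref", "alt", "aa")],
                      sample_ids = m$sample_ids, pop = m$pop,
                      polarized = m$polarized)
  out
}

#' Flag sites that fall inside a region set
#'
#' VCF positions are 1-based; BED intervals are 0-based half-open. The
#' conversion happens here and only here: a site is inside interval
#' `(start, end)` iff `pos - 1 >= start` and `pos - 1 < end`.
#'
#' @param sites data.frame with `chrom` and `pos` columns (or a
#'   [haplo_matrix()], whose site table is used).
#' @param regions a [region_set()].
#' @return logical vector, one flag per site.
#' @export
annotate_regions <- function(sites, regions) {
  if (inherits(sites, "haplo_matrix")) sites <- sites$sites
  stopifnot(inherits(regions, "region_set"))
  flags <- logical(nrow(sites))
  iv <- regions$intervals
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    d <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) {
      message("annotate_regions: chromosome ", ch,
              " absent from region set '", regions$label, "'")
      next
    }
    p0 <- sites$pos[si] - 1L
    k <- findInterval(p0, d$start)
    flags[si] <- k >= 1L & p0 < d$end[pmax(k, 1L)]
  }
  flags
}
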