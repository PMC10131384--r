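#' Phased haplotype matrix for one population
#'
#' The central container of the scan: a binary matrix of phased haplotypes
#' (rows) by polymorphic sites (columns) for a single population, with the
#' per-site metadata needed downstream. Entry coding is 0/1; after
#' [polarize_by_ancestral()] a 1 means the haplotype carries the derived
#' (non-ancestral) allele.
#'
#' @param entries integer matrix, `n_haplotypes x n_sites`, values in `{0,1}`.
#'   Two consecutive rows `2i-1, 2i` are the phased pair of diploid sample `i`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt` and optionally `aa` (ancestral allele, `NA` when unannotated).
#'   Positions must be strictly increasing within a chromosome.
#' @param sample_ids optional character vector, one id per diploid sample.
#' @param pop population label carried through every downstream statistic.
#' @param polarized logical; `TRUE` once entries are ancestral/derived coded.
#' @return an object of class `haplo_matrix`.
#' @export
haplo_matrix <- function(entries, sites, sample_ids = NULL, pop = "pop",
                         polarized = FALSE) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (ncol(entries) != nrow(sites))
    stop("entries has ", ncol(entries), " columns but sites has ",
         nrow(sites), " rows")
  if (nrow(sites) > 0) {
    if (anyNA(entries) || any(entries != 0L & entries != 1L))
      stop("haplotype entries must be 0/1 with no missing values")
    bad <- unlist(lapply(split(sites$pos, sites$chrom),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      stop("positions must be strictly increasing within a chromosome")
  }
  if (!is.null(sample_ids) && length(sample_ids) * 2L != nrow(entries))
    stop("need exactly 2 haplotype rows per sample id")
  if (!"aa" %in% names(sites)) sites$aa <- NA_character_
  f <- if (nrow(entries) > 0) colMeans(entries) else numeric(0)
  sites$derived_freq <- as.numeric(f)
  sites$maf <- pmin(sites$derived_freq, 1 - sites$derived_freq)
  rownames(sites) <- NULL
  structure(list(entries = entries, sites = sites, sample_ids = sample_ids,
                 pop = pop, polarized = isTRUE(polarized)),
            class = "haplo_matrix")
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat(sprintf("<haplo_matrix> pop=%s: %d haplotypes x %d sites%s\n",
              x$pop, nrow(x$entries), ncol(x$entries),
              if (x$polarized) " (polarized)" else ""))
  invisible(x)
}

#' @export
dim.haplo_matrix <- function(x) dim(x$entries)

#' Number of haplotype rows in a matrix
#' @param m a [haplo_matrix()].
#' @return integer count.
#' @export
n_haplotypes <- function(m) nrow(m$entries)

#' Number of sites (columns) in a matrix
#' @param m a [haplo_matrix()].
#' @return integer count.
#' @export
n_sites <- function(m) ncol(m$entries)

# shared-site-list check used by the cross-population statistics
check_shared_sites <- function(a, b) {
  if (!identical(a$sites$chrom, b$sites$chrom) ||
      !identical(a$sites$pos, b$sites$pos))
    stop("matrices do not share an identical site list")
  invisible(TRUE)
}
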