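#' @keywords internal
"_PACKAGE"

#' Chicken autosomal karyotype (gga1-gga28)
#'
#' Convenience constructor for the default autosome set used when reading
#' genotypes: chromosome labels `gga1` ... `gga28`. Variants on any other
#' contig (sex chromosomes, unplaced scaffolds) are dropped at read time
#' when this karyotype is declared.
#'
#' @return Character vector of 28 autosome labels.
#' @export
gga_autosomes <- function() paste0("gga", 1:28)

#' Construct a genotype matrix
#'
#' The canonical in-memory container used by every statistic in the
#' package: unphased diploid biallelic genotypes coded as the count of the
#' alternate allele (0 = hom-ref, 1 = het, 2 = hom-alt) with `NA` for
#' missing calls, together with a variant table carrying chromosome,
#' 1-based position and alleles.
#'
#' @param calls Integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `calls`. Positions must be strictly increasing
#'   within a chromosome; if not, variants are sorted (with a warning).
#' @param samples Character vector of sample identifiers; defaults to the
#'   rownames of `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix with sample rownames) and `variants`.
#' @export
genotype_matrix <- function(calls, variants, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(calls)))
  stopifnot(length(samples) == nrow(calls))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt")
  if (nrow(variants) != ncol(calls))
    stop("variants rows (", nrow(variants), ") != calls columns (", ncol(calls), ")")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (is.unsorted(ord) || any(ord != seq_along(ord))) {
    if (any(ord != seq_along(ord)))
      warning("variants not sorted by (chromosome, position); sorting")
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(calls) <- samples
  rownames(variants) <- NULL
  structure(list(calls = calls, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = " "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / variants
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_variants <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample index (logical, integer or character).
#' @param j Variant index.
#' @param ... Unused.
#' @return A `genotype_matrix` view.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  samples = rownames(x$calls)[if (is.character(i)) match(i, rownames(x$calls)) else i])
}

#' Per-variant alternate-allele frequency
#'
#' Frequency of the alternate allele among called gene copies; `NaN` for
#' variants with no calls.
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector, one entry per variant.
#' @export
allele_freq <- function(gm) {
  colSums(gm$calls, na.rm = TRUE) / (2 * colSums(!is.na(gm$calls)))
}

#' Per-variant minor allele frequency
#' @param gm A `genotype_matrix`.
#' @return Numeric vector in `[0, 0.5]`.
#' @export
maf <- function(gm) {
  p <- allele_freq(gm)
  pmin(p, 1 - p)
}

#' Split a genotype matrix by sub-population
#'
#' Partitions the samples into one genotype-matrix view per sub-population
#' (breed-by-generation pool in the conservation-monitoring design), with
#' the original sample order preserved within each view.
#'
#' @param gm A `genotype_matrix`.
#' @param map Sub-population map as returned by [read_subpop_map()]: a
#'   `data.frame` with columns `sample`, `subpop` and optionally `sex`.
#' @return Named list of `genotype_matrix` views, one per sub-population
#'   label (in order of first appearance in `map`).
#' @export
split_by_subpopulation <- function(gm, map) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("sample", "subpop") %in% names(map)))
    stop("map must have columns 'sample' and 'subpop'")
  if (nrow(map) == 0) stop("empty sub-population map")
  if (anyDuplicated(map$sample))
    stop("samples assigned to more than one sub-population: ",
         paste(unique(map$sample[duplicated(map$sample)]), collapse = ", "))
  missing_ids <- setdiff(map$sample, rownames(gm$calls))
  if (length(missing_ids))
    stop("mapped samples absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "))
  labs <- unique(map$subpop)
  out <- lapply(labs, function(lab) {
    ids <- map$sample[map$subpop == lab]
    keep <- rownames(gm$calls) %in% ids  # preserve gm order
    gm[keep, ]
  })
  names(out) <- labs
  out
}
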