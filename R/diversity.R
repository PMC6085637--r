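#' Observed heterozygosity
#'
#' Per-SNP fraction of called genotypes that are heterozygous, averaged
#' over SNPs. SNPs with no calls in the sub-population are excluded from
#' the average (their count is available via `attr(, "n_dropped")`).
#'
#' @param gm A `genotype_matrix`.
#' @return Mean observed heterozygosity in `[0, 1]`.
#' @export
observed_heterozygosity <- function(gm) {
  if (n_variants(gm) == 0) stop("empty genotype matrix")
  ncall <- colSums(!is.na(gm$calls))
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  ok <- ncall > 0
  if (!any(ok)) stop("no called genotypes")
  out <- mean(het[ok] / ncall[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Expected heterozygosity
#'
#' Per-SNP expected heterozygosity 2p(1-p), with p the alternate-allele
#' frequency among called alleles, averaged over SNPs. With
#' `unbiased = TRUE` each SNP is scaled by the small-sample factor
#' 2n/(2n-1) (Nei's unbiased estimator); the default is the plain 2pq
#' used by PLINK-style reports.
#'
#' @param gm A `genotype_matrix`.
#' @param unbiased Apply the 2n/(2n-1) correction.
#' @return Mean expected heterozygosity in `[0, 1]`.
#' @export
expected_heterozygosity <- function(gm, unbiased = FALSE) {
  if (n_variants(gm) == 0) stop("empty genotype matrix")
  ncall <- colSums(!is.na(gm$calls))
  ok <- ncall > 0
  if (!any(ok)) stop("no called genotypes")
  p <- allele_freq(gm)[ok]
  he <- 2 * p * (1 - p)
  if (unbiased) {
    nn <- 2 * ncall[ok]
    he <- he * nn / (nn - 1)
  }
  out <- mean(he)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Proportion of polymorphic SNPs
#'
#' Fraction of panel SNPs at which both alleles are observed (MAF > 0)
#' within the sub-population. The denominator is the full shared panel,
#' so sub-populations fixed at many panel SNPs score low even though the
#' fixed SNPs carry no within-population information.
#'
#' @param gm A `genotype_matrix` restricted to the sub-population, over
#'   the shared panel of SNPs.
#' @return P_N in `[0, 1]`.
#' @export
proportion_polymorphic <- function(gm) {
  m <- maf(gm)
  m[is.nan(m)] <- 0   # zero calls -> not observed polymorphic
  mean(m > 0)
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g` gene
#' copies without replacement, averaged over loci:
#' `sum_i (1 - choose(N - N_i, g) / choose(N, g))` with `N` called
#' copies at the locus and `N_i` copies of allele i. For biallelic SNPs
#' the result lies in `[1, 2]`. Standardizing `g` across sub-populations
#' makes richness comparable despite unequal sample sizes.
#'
#' @param gm A `genotype_matrix`.
#' @param g Standardized number of gene copies; must satisfy
#'   `1 <= g <= N` at every included locus.
#' @return Mean allelic richness.
#' @export
allelic_richness <- function(gm, g) {
  if (g < 1) stop("g must be >= 1")
  ncall <- colSums(!is.na(gm$calls))
  ok <- ncall > 0
  if (!any(ok)) stop("no called genotypes")
  N <- 2 * ncall[ok]
  if (any(g > N))
    stop("g = ", g, " exceeds called gene copies at locus (first): ",
         which(ok)[which(g > N)[1]])
  nalt <- colSums(gm$calls, na.rm = TRUE)[ok]
  nref <- N - nalt
  # P(allele absent from a g-subsample) = C(N - N_i, g) / C(N, g)
  absent <- function(ni) exp(lchoose(N - ni, g) - lchoose(N, g))
  mean((1 - absent(nref)) + (1 - absent(nalt)))
}

#' Default standardized gene-copy count for allelic richness
#'
#' Twice the smallest sub-population sample size scaled by the maximum
#' allowed missing-call fraction, floored.
#'
#' @param subpops List of `genotype_matrix` objects being compared.
#' @param max_missing Assumed worst-case per-SNP missing fraction.
#' @return Integer g.
#' @export
default_richness_g <- function(subpops, max_missing = 0.05) {
  nmin <- min(vapply(subpops, n_samples, integer(1)))
  max(1L, floor(2 * nmin * (1 - max_missing)))
}

#' Windowed nucleotide diversity
#'
#' Per-site pairwise diversity `2 * c_ref * c_alt / (c * (c - 1))` (with
#' c called alleles) summed over SNPs in each sliding window and divided
#' by the window size in bp, in the manner of vcftools' `--window-pi`.
#' Windows are anchored at position 1 on each chromosome; the final
#' partial window keeps the nominal window-size divisor.
#'
#' @param gm A `genotype_matrix`.
#' @param window_bp Window size (default 100 kb).
#' @param step_bp Step between window starts (default 10 kb).
#' @return `data.frame` with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `pi`, `n_sites`. Attribute `n_skipped` counts sites with
#'   fewer than two called alleles.
#' @export
nucleotide_diversity_windows <- function(gm, window_bp = 100000,
                                         step_bp = 10000) {
  stopifnot(window_bp > 0, step_bp > 0)
  ncall <- colSums(!is.na(gm$calls))
  c2 <- 2 * ncall
  nalt <- colSums(gm$calls, na.rm = TRUE)
  usable <- c2 >= 2
  pi_s <- numeric(ncol(gm$calls))
  pi_s[usable] <- 2 * nalt[usable] * (c2[usable] - nalt[usable]) /
    (c2[usable] * (c2[usable] - 1))
  out <- list()
  for (chr in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == chr & usable)
    pos <- gm$variants$pos[idx]
    maxpos <- max(gm$variants$pos[gm$variants$chrom == chr])
    starts <- seq(1, max(1, maxpos), by = step_bp)
    ends <- starts + window_bp - 1
    first <- findInterval(starts - 1, pos) + 1L
    last <- findInterval(ends, pos)
    cs <- c(0, cumsum(pi_s[idx]))
    n_in <- pmax(last - first + 1L, 0L)
    s <- ifelse(n_in > 0, cs[last + 1L] - cs[first], 0)
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             pi = s / window_bp, n_sites = n_in,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- sum(!usable)
  res
}

#' Per-subpopulation diversity summary
#'
#' One row per sub-population with Ho, He, P_N and (optionally) A_R,
#' mirroring the layout of a diversity-monitoring report table.
#'
#' @param subpops Named list of `genotype_matrix` objects sharing a panel.
#' @param g Gene-copy count for allelic richness; `NULL` uses
#'   [default_richness_g()]. `NA` skips A_R.
#' @return `data.frame` with columns `subpop`, `Ho`, `He`, `P_N`, `A_R`
#'   and attribute `richness_g`.
#' @export
diversity_summary <- function(subpops, g = NULL) {
  if (is.null(g)) g <- default_richness_g(subpops)
  rows <- lapply(names(subpops), function(lab) {
    gmp <- subpops[[lab]]
    data.frame(subpop = lab,
               Ho = as.numeric(observed_heterozygosity(gmp)),
               He = as.numeric(expected_heterozygosity(gmp)),
               P_N = proportion_polymorphic(gmp),
               A_R = if (is.na(g)) NA_real_ else allelic_richness(gmp, g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "richness_g") <- g
  out
}

#' Generational trend report
#'
#' Relative change of each diversity metric against the first sampled
#' generation, with the two conservation flags: `retention_ok` when every
#' metric retains at least `retention` (default 90%) of its
#' first-generation value, and `inbreeding_ok` when all supplied
#' inbreeding coefficients stay below `f_max` (default 0.1).
#'
#' @param summaries `data.frame` as from [diversity_summary()], rows
#'   ordered by generation (earliest first), for one breed.
#' @param f_values Optional numeric vector of inbreeding coefficients
#'   (any mix of mating-plan and ROH-based values) to check against
#'   `f_max`.
#' @param retention Retention threshold (fraction of first-generation
#'   value).
#' @param f_max Inbreeding ceiling.
#' @return List with `changes` (data.frame of relative changes per
#'   generation and metric; `NA` where the baseline is 0), `retention_ok`,
#'   `inbreeding_ok` (`NA` if no `f_values` given).
#' @export
generational_trend <- function(summaries, f_values = NULL,
                               retention = 0.9, f_max = 0.1) {
  if (nrow(summaries) < 2) stop("need >= 2 generations")
  metrics <- intersect(c("Ho", "He", "P_N", "A_R"), names(summaries))
  metrics <- metrics[vapply(metrics, function(m)
    !all(is.na(summaries[[m]])), logical(1))]
  base <- summaries[1, metrics, drop = FALSE]
  rel <- sweep(as.matrix(summaries[metrics]), 2, as.numeric(base), "-")
  rel <- sweep(rel, 2, as.numeric(base), "/")
  rel[, as.numeric(base) == 0] <- NA
  changes <- data.frame(subpop = summaries$subpop, rel,
                        stringsAsFactors = FALSE)
  ratio <- sweep(as.matrix(summaries[metrics]), 2, as.numeric(base), "/")
  retention_ok <- all(ratio >= retention, na.rm = TRUE) &&
    !any(as.numeric(base) == 0 & colSums(as.matrix(summaries[metrics])) > 0)
  inbreeding_ok <- if (is.null(f_values)) NA else all(f_values < f_max)
  list(changes = changes, retention_ok = retention_ok,
       inbreeding_ok = inbreeding_ok)
}
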