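#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic locus: enumerates every possible
#' heterozygote count conditional on the observed allele counts and sums
#' the probabilities of all configurations no more likely than the
#' observed one (the standard, non-mid-p definition).
#'
#' @param n_hom_ref,n_het,n_hom_alt Observed genotype counts.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no genotypes observed")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het   # rare allele copies
  if (n_rare == 0) return(1.0)                      # monomorphic
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het = h | allele counts): multinomial/hypergeometric kernel
  rare_hom <- (n_rare - hets) / 2
  com_hom <- n - hets - rare_hom
  logp <- lfactorial(n) - lfactorial(hets) - lfactorial(rare_hom) -
    lfactorial(com_hom) + hets * log(2) +
    lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' QC thresholds
#'
#' Defaults follow common SNP-array/GBS practice: per-SNP call rate at
#' least 95%, minor allele frequency at least 0.05, Hardy-Weinberg exact
#' p-value above 1e-6; samples with more than 1% missing calls are
#' flagged (not dropped).
#'
#' @param min_call_rate Minimum fraction of samples called per SNP.
#' @param min_maf Minimum minor allele frequency.
#' @param hwe_alpha HWE exact-test p-value floor.
#' @param max_missing_rate Per-sample missing-call fraction above which a
#'   sample is flagged in the report.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                          hwe_alpha = 1e-6, max_missing_rate = 0.01) {
  vals <- c(min_call_rate, min_maf, hwe_alpha, max_missing_rate)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, max_missing_rate = max_missing_rate),
            class = "qc_thresholds")
}

#' Apply SNP quality control
#'
#' Removes SNPs failing the Hardy-Weinberg exact test, the minor-allele-
#' frequency floor, or the per-SNP call-rate floor. Each excluded SNP is
#' counted once, under the first criterion it fails, in the order
#' HWE, then MAF, then call rate, so the report's category counts are
#' exclusive and sum to the number excluded.
#'
#' @param gm A `genotype_matrix`.
#' @param thr A [qc_thresholds()] object.
#' @return List with elements `gm` (filtered `genotype_matrix`), and
#'   `report`: counts `input`, `retained`, `excluded_hwe`, `excluded_maf`,
#'   `excluded_call`, the thresholds used, and `flagged_samples` (IDs
#'   above the per-sample missing-rate limit).
#' @export
apply_qc <- function(gm, thr = qc_thresholds()) {
  stopifnot(inherits(thr, "qc_thresholds"))
  if (n_variants(gm) == 0) stop("empty genotype matrix")
  calls <- gm$calls
  ncall <- colSums(!is.na(calls))
  if (any(ncall == 0)) {
    # SNPs with no calls at all fail call rate trivially; HWE undefined
    hwe_p <- rep(1, ncol(calls))
    idx <- ncall > 0
  } else idx <- rep(TRUE, ncol(calls))
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  hwe_p <- rep(1, ncol(calls))
  hwe_p[idx] <- vapply(which(idx), function(j)
    hwe_exact_test(n0[j], n1[j], n2[j]), numeric(1))
  mafs <- pmin(1, pmax(0, (n1 + 2 * n2) / (2 * pmax(ncall, 1L))))
  mafs <- pmin(mafs, 1 - mafs)
  mafs[ncall == 0] <- 0
  call_rate <- ncall / nrow(calls)

  fail_hwe <- hwe_p <= thr$hwe_alpha
  fail_maf <- !fail_hwe & (mafs < thr$min_maf)
  fail_call <- !fail_hwe & !fail_maf & (call_rate < thr$min_call_rate)
  keep <- !(fail_hwe | fail_maf | fail_call)

  sample_miss <- rowMeans(is.na(calls))
  report <- list(input = ncol(calls), retained = sum(keep),
                 excluded_hwe = sum(fail_hwe), excluded_maf = sum(fail_maf),
                 excluded_call = sum(fail_call),
                 thresholds = unclass(thr),
                 flagged_samples = rownames(calls)[sample_miss > thr$max_missing_rate])
  list(gm = gm[, keep], report = report)
}

#' LD-pruning parameters
#'
#' Windowed greedy pruning in the style of PLINK's
#' `--indep-pairwise 50 5 0.2`: a 50-SNP window stepped by 5 SNPs, with
#' pairs above genotype-correlation r-squared 0.2 reduced by dropping the
#' lower-MAF member.
#'
#' @param window_snps Window width in SNPs.
#' @param step_snps Step between successive windows, in SNPs.
#' @param r2_threshold Maximum tolerated pairwise r-squared.
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_snps = 50, step_snps = 5, r2_threshold = 0.2) {
  stopifnot(window_snps >= 2, step_snps >= 1, step_snps <= window_snps,
            r2_threshold > 0, r2_threshold < 1)
  structure(list(window_snps = window_snps, step_snps = step_snps,
                 r2_threshold = r2_threshold), class = "prune_params")
}

#' Greedy windowed LD pruning
#'
#' Within each window, while any retained pair of SNPs has genotype
#' (composite) r-squared above the threshold, the member of the worst
#' pair with the lower MAF is removed (ties broken towards the later
#' position); the window then advances by `step_snps`. Chromosomes are
#' pruned independently.
#'
#' @param gm A `genotype_matrix` (normally already quality-controlled).
#' @param p A [prune_params()] object.
#' @return Integer vector of retained variant indices (increasing).
#' @export
ld_prune <- function(gm, p = prune_params()) {
  stopifnot(inherits(p, "prune_params"))
  calls <- gm$calls
  mafs <- maf(gm)
  pos <- gm$variants$pos
  keep <- rep(TRUE, ncol(calls))
  for (chr in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == chr)
    n <- length(idx)
    i <- 1L
    repeat {
      win <- idx[i:min(i + p$window_snps - 1L, n)]
      act <- win[keep[win]]
      if (length(act) >= 2) {
        r2 <- suppressWarnings(
          stats::cor(calls[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        while (max(r2) > p$r2_threshold) {
          w <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          a <- act[w[1]]; b <- act[w[2]]
          drop <- if (mafs[a] < mafs[b]) a
                  else if (mafs[b] < mafs[a]) b
                  else if (pos[a] > pos[b]) a else b
          keep[drop] <- FALSE
          di <- which(act == drop)
          r2[di, ] <- 0; r2[, di] <- 0
        }
      }
      if (i + p$window_snps - 1L >= n) break
      i <- i + p$step_snps
    }
  }
  which(keep)
}
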