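# Genotype-class count tables for a set of locus pairs, via indicator
# cross-products: entry (x, y) of the 3x3 table for pair (a, b) is
# crossprod(I_x, I_y)[a, b]. Returns a list of 9 m x m matrices.
pair_count_tables <- function(calls) {
  I <- lapply(0:2, function(g) {
    m <- calls == g
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  out <- list()
  for (x in 0:2) for (y in 0:2)
    out[[paste0("n", x, y)]] <- crossprod(I[[x + 1]], I[[y + 1]])
  out
}

# Vectorized EM for haplotype frequencies of unphased diploid pairs.
# n** are vectors of genotype-class counts (one entry per pair).
# Returns list(r2, D, pA, pB, n) with NA where a locus is monomorphic.
em_r2_vec <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                      tol = 1e-8, max_iter = 1000,
                      starts = c(0.5, 0.05, 0.95)) {
  n <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  np <- length(n00)
  best_ll <- rep(-Inf, np)
  best <- matrix(NA_real_, np, 4,
                 dimnames = list(NULL, c("frr", "fra", "far", "faa")))
  k_rr <- 2 * n00 + n01 + n10
  k_ra <- n01 + 2 * n02 + n12
  k_ar <- n10 + 2 * n20 + n21
  k_aa <- n12 + n21 + 2 * n22
  for (x0 in starts) {
    x <- rep(x0, np)
    f <- cbind(frr = (k_rr + x * n11) / (2 * n),
               fra = (k_ra + (1 - x) * n11) / (2 * n),
               far = (k_ar + (1 - x) * n11) / (2 * n),
               faa = (k_aa + x * n11) / (2 * n))
    for (it in seq_len(max_iter)) {
      denom <- f[, "frr"] * f[, "faa"] + f[, "fra"] * f[, "far"]
      x <- ifelse(denom > 0, f[, "frr"] * f[, "faa"] / denom, 0.5)
      fn <- cbind(frr = (k_rr + x * n11) / (2 * n),
                  fra = (k_ra + (1 - x) * n11) / (2 * n),
                  far = (k_ar + (1 - x) * n11) / (2 * n),
                  faa = (k_aa + x * n11) / (2 * n))
      if (max(abs(fn - f)) < tol) { f <- fn; break }
      f <- fn
    }
    ll <- em_loglik(f, n00, n01, n02, n10, n11, n12, n20, n21, n22)
    upd <- ll > best_ll + 1e-12
    best[upd, ] <- f[upd, ]
    best_ll[upd] <- ll[upd]
  }
  pA <- best[, "far"] + best[, "faa"]   # alt freq, locus 1
  pB <- best[, "fra"] + best[, "faa"]   # alt freq, locus 2
  D <- best[, "faa"] - pA * pB
  poly <- pA > 0 & pA < 1 & pB > 0 & pB < 1
  r2 <- rep(NA_real_, np)
  r2[poly] <- D[poly]^2 / (pA[poly] * (1 - pA[poly]) * pB[poly] * (1 - pB[poly]))
  list(r2 = r2, D = D, pA = pA, pB = pB, n = n)
}

# Multinomial log-likelihood of the nine genotype classes given
# haplotype frequencies (rows of f).
em_loglik <- function(f, n00, n01, n02, n10, n11, n12, n20, n21, n22) {
  frr <- f[, 1]; fra <- f[, 2]; far <- f[, 3]; faa <- f[, 4]
  lg <- function(p) log(pmax(p, 1e-300))
  n00 * lg(frr^2) + n01 * lg(2 * frr * fra) + n02 * lg(fra^2) +
    n10 * lg(2 * frr * far) +
    n11 * lg(2 * frr * faa + 2 * fra * far) +
    n12 * lg(2 * fra * faa) +
    n20 * lg(far^2) + n21 * lg(2 * far * faa) + n22 * lg(faa^2)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' LD between two loci of a genotype matrix. The `"em"` method fits
#' maximum-likelihood haplotype frequencies for unphased diploids by EM
#' (tolerance 1e-8, at most 1000 iterations, three starts) and returns
#' `D^2 / (pA pa pB pb)`; the `"composite"` method returns the squared
#' Pearson correlation of genotype codes.
#'
#' @param gm A `genotype_matrix`.
#' @param locus_a,locus_b Variant indices.
#' @param method `"em"` or `"composite"`.
#' @return r-squared in `[0, 1]`, or `NA` when either locus is
#'   monomorphic among individuals called at both.
#' @export
pairwise_r2 <- function(gm, locus_a, locus_b, method = c("em", "composite")) {
  method <- match.arg(method)
  ga <- gm$calls[, locus_a]; gb <- gm$calls[, locus_b]
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) stop("need >= 2 individuals called at both loci")
  ga <- ga[ok]; gb <- gb[ok]
  if (stats::var(ga) == 0 || stats::var(gb) == 0) return(NA_real_)
  if (method == "composite") return(stats::cor(ga, gb)^2)
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  em_r2_vec(tab[1, 1], tab[1, 2], tab[1, 3],
            tab[2, 1], tab[2, 2], tab[2, 3],
            tab[3, 1], tab[3, 2], tab[3, 3])$r2
}

# All intra-chromosomal pairs within max_distance_bp, with r2.
# Returns data.frame(chrom, dist, r2).
ld_pair_table <- function(gm, max_distance_bp, method) {
  out <- list()
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    if (length(idx) < 2) next
    pos <- gm$variants$pos[idx]
    hi <- findInterval(pos + max_distance_bp, pos)   # last partner per i
    i_v <- rep.int(seq_along(pos), pmax(hi - seq_along(pos), 0L))
    j_v <- unlist(lapply(seq_along(pos),
                         function(i) if (hi[i] > i) (i + 1L):hi[i] else integer(0)))
    if (!length(i_v)) next
    pr <- cbind(i_v, j_v)
    calls <- gm$calls[, idx, drop = FALSE]
    if (method == "em") {
      ct <- pair_count_tables(calls)
      sel <- cbind(pr[, 1], pr[, 2])
      r2 <- em_r2_vec(ct$n00[sel], ct$n01[sel], ct$n02[sel],
                      ct$n10[sel], ct$n11[sel], ct$n12[sel],
                      ct$n20[sel], ct$n21[sel], ct$n22[sel])$r2
    } else {
      cm <- suppressWarnings(stats::cor(calls, use = "pairwise.complete.obs"))^2
      r2 <- cm[cbind(pr[, 1], pr[, 2])]
    }
    out[[ch]] <- data.frame(chrom = ch,
                            dist = pos[pr[, 2]] - pos[pr[, 1]],
                            r2 = r2, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chrom = character(), dist = numeric(),
                                      r2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LD decay curve and half-maximum decay distance
#'
#' Bins all intra-chromosomal locus pairs within `max_distance_bp` by
#' physical distance, averages r-squared per bin, and reports the
#' distance at which the binned curve first falls below half of its
#' maximum bin mean (linear interpolation between the bracketing bin
#' midpoints). Five equal-width bins over 0-500 kb is the conventional
#' consolidation for genome-wide chicken panels.
#'
#' @param gm A `genotype_matrix` (already MAF/HWE filtered).
#' @param max_distance_bp Maximum inter-SNP distance (default 500 kb).
#' @param bins Number of equal-width distance bins (default 5).
#' @param method r-squared estimator, see [pairwise_r2()]; EM by
#'   default, the convention for decay curves.
#' @return List of class `decay_curve`: `bins` (data.frame with
#'   `bin_start`, `bin_end`, `mid`, `mean_r2`, `n_pairs`) and
#'   `half_decay_bp` (`Inf` when the curve never falls below half its
#'   maximum within range; `NA` when undefined, e.g. a single usable
#'   bin).
#' @export
ld_decay <- function(gm, max_distance_bp = 500000, bins = 5,
                     method = c("em", "composite")) {
  method <- match.arg(method)
  stopifnot(bins >= 1)
  pt <- ld_pair_table(gm, max_distance_bp, method)
  edges <- seq(0, max_distance_bp, length.out = bins + 1)
  bin <- cut(pt$dist, edges, include.lowest = TRUE, labels = FALSE)
  tab <- data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1])
  tab$mid <- (tab$bin_start + tab$bin_end) / 2
  tab$mean_r2 <- NA_real_
  tab$n_pairs <- 0L
  if (nrow(pt)) {
    ok <- !is.na(pt$r2)
    agg_m <- tapply(pt$r2[ok], bin[ok], mean)
    agg_n <- tapply(pt$r2[ok], bin[ok], length)
    ix <- as.integer(names(agg_m))
    tab$mean_r2[ix] <- agg_m
    tab$n_pairs[ix] <- agg_n
  }
  used <- which(!is.na(tab$mean_r2))
  if (length(used) < nrow(tab) && length(used) > 0)
    warning(nrow(tab) - length(used), " empty bin(s) excluded")
  half_decay <- NA_real_
  if (length(used) >= 2) {
    m <- tab$mean_r2[used]; mid <- tab$mid[used]
    half <- max(m) / 2
    imax <- which.max(m)
    below <- which(m < half & seq_along(m) > imax)
    if (!length(below)) half_decay <- Inf
    else {
      j <- below[1]
      i <- j - 1
      half_decay <- mid[i] + (mid[j] - mid[i]) * (m[i] - half) / (m[i] - m[j])
    }
  }
  structure(list(bins = tab, half_decay_bp = half_decay, method = method),
            class = "decay_curve")
}

# Waples (2006) sample-size bias correction and random-mating LD-Ne.
waples_ne <- function(r2_mean, S) {
  if (S >= 30) {
    r2p <- r2_mean - 1 / S - 3.19 / S^2
    a <- 1 / 3; b <- 2.76
  } else {
    r2p <- r2_mean - (0.0018 + 0.907 / S + 4.44 / S^2)
    a <- 0.308; b <- 2.08
  }
  if (is.na(r2p) || r2p <= 0) return(list(ne = Inf, r2_prime = r2p))
  disc <- a^2 - b * r2p
  if (disc < 0) return(list(ne = Inf, r2_prime = r2p))
  list(ne = (a + sqrt(disc)) / (2 * r2p), r2_prime = r2p)
}

# Chromosome size class from a label like "gga7" or "chr7".
chrom_class <- function(label) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", label)))
  ifelse(is.na(num), NA_character_,
         ifelse(num <= 5, "macro", ifelse(num <= 10, "intermediate", "micro")))
}

#' LD-based effective population size
#'
#' Per-chromosome Ne under the random-mating linkage-disequilibrium
#' model: the mean composite r-squared over intra-chromosomal locus
#' pairs is corrected for sample size with the Waples (2006) adjustment
#' (`r2' = r2 - 1/S - 3.19/S^2` for S >= 30, the published small-sample
#' coefficients otherwise), and inverted as
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`. Chromosomes where the
#' corrected r-squared is non-positive get an infinite-Ne flag and are
#' excluded from class averages. Classes follow the chicken karyotype
#' convention: macro (gga1-5), intermediate (gga6-10), micro (gga11-28).
#'
#' @param gm A `genotype_matrix` for one sub-population.
#' @param maf_cutoff Minimum MAF for included loci (default 0.05).
#' @param max_pairs_per_chrom Optional cap on pairs per chromosome
#'   (pairs subsampled deterministically by even spacing when exceeded).
#' @return List of class `ne_estimate`: `per_chromosome` (data.frame
#'   `chrom`, `class`, `n_loci`, `n_pairs`, `S`, `r2_mean`, `r2_prime`,
#'   `ne`), `class_averages` (named vector: macro, intermediate, micro,
#'   overall; averages of finite per-chromosome Ne), and
#'   `n_infinite`.
#' @export
ne_from_ld <- function(gm, maf_cutoff = 0.05, max_pairs_per_chrom = Inf) {
  if (n_samples(gm) < 10) stop("need >= 10 individuals")
  keep <- maf(gm) >= maf_cutoff & !is.nan(maf(gm))
  gm2 <- gm[, keep]
  rows <- list()
  for (ch in unique(gm2$variants$chrom)) {
    idx <- which(gm2$variants$chrom == ch)
    if (length(idx) < 2) next
    calls <- gm2$calls[, idx, drop = FALSE]
    cm <- suppressWarnings(stats::cor(calls, use = "pairwise.complete.obs"))^2
    nm <- crossprod(!is.na(calls))
    ut <- upper.tri(cm)
    r2v <- cm[ut]; nv <- nm[ut]
    ok <- !is.na(r2v) & nv >= 2
    r2v <- r2v[ok]; nv <- nv[ok]
    if (length(r2v) > max_pairs_per_chrom) {
      sel <- round(seq(1, length(r2v), length.out = max_pairs_per_chrom))
      r2v <- r2v[sel]; nv <- nv[sel]
    }
    if (!length(r2v)) next
    S <- mean(nv)
    w <- waples_ne(mean(r2v), S)
    rows[[ch]] <- data.frame(chrom = ch, class = chrom_class(ch),
                             n_loci = length(idx), n_pairs = length(r2v),
                             S = S, r2_mean = mean(r2v),
                             r2_prime = w$r2_prime, ne = w$ne,
                             stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  finite <- per[is.finite(per$ne), ]
  avg_of <- function(cl) {
    v <- finite$ne[finite$class %in% cl]
    if (length(v)) mean(v) else NA_real_
  }
  class_averages <- c(macro = avg_of("macro"),
                      intermediate = avg_of("intermediate"),
                      micro = avg_of("micro"),
                      overall = avg_of(c("macro", "intermediate", "micro")))
  structure(list(per_chromosome = per, class_averages = class_averages,
                 n_infinite = sum(!is.finite(per$ne))),
            class = "ne_estimate")
}
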