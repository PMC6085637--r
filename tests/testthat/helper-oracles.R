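# Independent enumeration oracle for the HWE exact test: exact integer
# combinatorics over all genotype configurations compatible with the
# allele counts.
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- n1 + 2 * n2
  cfgs <- expand.grid(a1 = 0:n, a2 = 0:n)
  cfgs <- cfgs[cfgs$a1 + 2 * cfgs$a2 == nA & cfgs$a1 + cfgs$a2 <= n, ]
  ways <- mapply(function(a1, a2) {
    a0 <- n - a1 - a2
    choose(n, a1) * choose(n - a1, a2) * 2^a1
  }, cfgs$a1, cfgs$a2)
  probs <- ways / sum(ways)
  obs <- which(cfgs$a1 == n1 & cfgs$a2 == n2)
  sum(probs[probs <= probs[obs] * (1 + 1e-9)])
}


# Literal, unoptimized transcription of the three-phase window-scan
# definition (per-anchor subsetting), used as the oracle for the
# prefix-sum detector.
roh_oracle_chrom <- function(geno, pos, p) {
  n <- length(geno)
  hom_win <- logical(n)
  for (j in seq_len(n)) {
    w <- which(pos >= pos[j] & pos <= pos[j] + p$window_bp - 1)
    hom_win[j] <- sum(geno[w] == 1, na.rm = TRUE) <= p$max_het_per_window &&
      sum(is.na(geno[w])) <= p$max_missing_per_window
  }
  elig <- vapply(seq_len(n), function(s) {
    anchors <- which(pos <= pos[s] & pos > pos[s] - p$window_bp)
    mean(hom_win[anchors]) >= p$hit_fraction
  }, logical(1))
  segs <- NULL
  run <- integer(0)
  flush <- function(run, segs) {
    if (length(run) == 0) return(segs)
    len <- pos[run[length(run)]] - pos[run[1]] + 1
    if (len >= p$min_length_bp && length(run) >= p$min_snps &&
        (len / 1000) / length(run) <= p$max_density_kb_per_snp)
      segs <- rbind(segs, data.frame(start = pos[run[1]],
                                     end = pos[run[length(run)]],
                                     n_snps = length(run)))
    segs
  }
  for (s in seq_len(n)) {
    if (elig[s]) {
      if (length(run) && pos[s] - pos[run[length(run)]] > p$max_gap_bp) {
        segs <- flush(run, segs); run <- integer(0)
      }
      run <- c(run, s)
    } else {
      segs <- flush(run, segs); run <- integer(0)
    }
  }
  flush(run, segs)
}


# Independent grid-search oracle: the two-locus likelihood is
# one-dimensional in the (alt, alt) haplotype frequency once the allele
# frequencies are fixed at their observed values; maximize it over a fine
# grid (two-stage refinement).
grid_r2 <- function(gA, gB) {
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  tab <- table(factor(gA, 0:2), factor(gB, 0:2))
  loglik <- function(f11) {
    faa <- f11; far <- pA - f11; fra <- pB - f11
    frr <- 1 - pA - pB + f11
    if (min(faa, far, fra, frr) < -1e-12) return(-Inf)
    lg <- function(x) log(max(x, 1e-300))
    tab[1, 1] * lg(frr^2) + tab[1, 2] * lg(2 * frr * fra) +
      tab[1, 3] * lg(fra^2) + tab[2, 1] * lg(2 * frr * far) +
      tab[2, 2] * lg(2 * frr * faa + 2 * fra * far) +
      tab[2, 3] * lg(2 * fra * faa) + tab[3, 1] * lg(far^2) +
      tab[3, 2] * lg(2 * far * faa) + tab[3, 3] * lg(faa^2)
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  g <- seq(lo, hi, length.out = 2001)
  best <- g[which.max(vapply(g, loglik, numeric(1)))]
  g2 <- seq(max(lo, best - (hi - lo) / 1000), min(hi, best + (hi - lo) / 1000),
            length.out = 2001)
  f11 <- g2[which.max(vapply(g2, loglik, numeric(1)))]
  D <- f11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}


hap_sample <- function(n, freqs, seed) {
  set.seed(seed)
  hapA <- c(1, 1, 0, 0); hapB <- c(1, 0, 1, 0)
  h1 <- sample(4, n, TRUE, prob = freqs)
  h2 <- sample(4, n, TRUE, prob = freqs)
  list(gA = hapA[h1] + hapA[h2], gB = hapB[h1] + hapB[h2])
}

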