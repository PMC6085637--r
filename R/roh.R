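#' ROH detection parameters
#'
#' Sliding-window criteria for calling runs of homozygosity: a 1 Mb
#' window slid across each chromosome, allowing at most one heterozygous
#' and five missing calls per window; candidate runs must span at least
#' 100 kb and 50 SNPs. The eligibility fraction, maximum inter-SNP gap
#' and maximum inverse density follow the conventional defaults of
#' PLINK-style detectors and are recorded in segment output.
#'
#' @param window_bp Window length in bp (default 1e6).
#' @param max_het_per_window Heterozygous calls tolerated per window.
#' @param max_missing_per_window Missing calls tolerated per window.
#' @param min_length_bp Minimum segment length.
#' @param min_snps Minimum SNPs per segment.
#' @param hit_fraction Minimum fraction of homozygous windows covering a
#'   SNP for it to be eligible.
#' @param max_gap_bp Segments are split at inter-SNP gaps above this.
#' @param max_density_kb_per_snp Maximum segment kb per SNP.
#' @param window_mode `"bp"` (window defined by physical length, the
#'   default) or `"snps"` (fixed SNP-count window, for parity with
#'   SNP-count-windowed tools).
#' @param window_snps Window size in SNPs when `window_mode = "snps"`.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_bp = 1e6, max_het_per_window = 1,
                       max_missing_per_window = 5, min_length_bp = 1e5,
                       min_snps = 50, hit_fraction = 0.05,
                       max_gap_bp = 1e6, max_density_kb_per_snp = 50,
                       window_mode = c("bp", "snps"), window_snps = 50) {
  window_mode <- match.arg(window_mode)
  stopifnot(window_bp > 0, min_length_bp > 0, min_snps >= 1,
            hit_fraction > 0, hit_fraction <= 1, max_gap_bp > 0,
            max_density_kb_per_snp > 0, window_snps >= 1)
  structure(list(window_bp = window_bp,
                 max_het_per_window = max_het_per_window,
                 max_missing_per_window = max_missing_per_window,
                 min_length_bp = min_length_bp, min_snps = min_snps,
                 hit_fraction = hit_fraction, max_gap_bp = max_gap_bp,
                 max_density_kb_per_snp = max_density_kb_per_snp,
                 window_mode = window_mode, window_snps = window_snps),
            class = "roh_params")
}

# Window-scan ROH calling for one individual on one chromosome.
# geno: 0/1/2/NA vector; pos: sorted positions. Returns data.frame of
# segments (start, end, n_snps).
roh_scan_chrom <- function(geno, pos, p) {
  n <- length(geno)
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be sorted")
  het_cs <- c(0, cumsum(geno == 1L & !is.na(geno)))
  mis_cs <- c(0, cumsum(is.na(geno)))
  if (p$window_mode == "bp") {
    last <- findInterval(pos + p$window_bp - 1, pos)   # window end index
    anchors <- seq_len(n)
    first_cov <- findInterval(pos - p$window_bp, pos) + 1L
    last_cov <- anchors                                # anchors j <= s cover s
  } else {
    ws <- min(p$window_snps, n)
    anchors <- seq_len(n - ws + 1L)
    last <- anchors + ws - 1L
    first_cov <- pmax(1L, seq_len(n) - ws + 1L)
    last_cov <- pmin(seq_len(n), n - ws + 1L)
  }
  hom_win <- (het_cs[last + 1L] - het_cs[anchors]) <= p$max_het_per_window &
    (mis_cs[last + 1L] - mis_cs[anchors]) <= p$max_missing_per_window
  hom_cs <- c(0, cumsum(hom_win))
  n_cov <- last_cov - first_cov + 1L
  n_hom <- hom_cs[last_cov + 1L] - hom_cs[first_cov]
  eligible <- n_cov > 0 & (n_hom / pmax(n_cov, 1L)) >= p$hit_fraction
  if (!any(eligible)) return(NULL)
  # maximal runs of eligible SNPs, split at large gaps
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    gaps <- diff(pos[idx])
    brk <- which(gaps > p$max_gap_bp)
    piece_start <- c(i0, idx[brk + 1L])
    piece_end <- c(idx[brk], i1)
    for (q in seq_along(piece_start)) {
      a <- piece_start[q]; b <- piece_end[q]
      len <- pos[b] - pos[a] + 1
      ns <- b - a + 1L
      if (len >= p$min_length_bp && ns >= p$min_snps &&
          (len / 1000) / ns <= p$max_density_kb_per_snp)
        segs[[length(segs) + 1L]] <- c(start = pos[a], end = pos[b],
                                       n_snps = ns)
    }
  }
  if (!length(segs)) return(NULL)
  as.data.frame(do.call(rbind, segs))
}

#' Detect runs of homozygosity
#'
#' Three-phase window scan per individual and chromosome: (1) every
#' window anchored at a SNP is scored homozygous iff it contains at most
#' `max_het_per_window` heterozygous and `max_missing_per_window` missing
#' calls; (2) a SNP is eligible iff at least `hit_fraction` of the
#' windows covering it are homozygous; (3) maximal runs of consecutive
#' eligible SNPs, split at gaps above `max_gap_bp`, become segments if
#' they pass the length, SNP-count and density filters. Segment
#' boundaries are the first and last SNP positions of the run.
#'
#' @param gm A `genotype_matrix`.
#' @param params A [roh_params()] object.
#' @return `data.frame` with columns `sample`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_snps`, `length_bp`, sorted by
#'   (sample, chrom, start).
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  out <- list()
  chroms <- unique(gm$variants$chrom)
  chr_idx <- lapply(chroms, function(ch) which(gm$variants$chrom == ch))
  names(chr_idx) <- chroms
  for (s in rownames(gm$calls)) {
    for (ch in chroms) {
      idx <- chr_idx[[ch]]
      segs <- roh_scan_chrom(gm$calls[s, idx], gm$variants$pos[idx], params)
      if (!is.null(segs)) {
        segs$sample <- s; segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$length_bp <- res$end - res$start + 1
  res <- res[order(res$sample, res$chrom, res$start),
             c("sample", "chrom", "start", "end", "n_snps", "length_bp")]
  rownames(res) <- NULL
  res
}

#' Summarize runs of homozygosity per population
#'
#' Per-individual totals (NSEG: number of segments; KB: summed length in
#' kb; KB_AVER: mean segment length in kb; NSNP: mean SNPs per segment;
#' density: mean kb per SNP) and PHOM, the genome-wide fraction of an
#' individual's called genotypes that are homozygous; then the
#' mean/SD/min/max of each measure across individuals. Individuals with
#' no segments contribute zeros.
#'
#' @param segments `data.frame` from [detect_roh()].
#' @param gm The `genotype_matrix` the segments were called on (used for
#'   the sample list and PHOM); alternatively pass `samples` explicitly
#'   and PHOM is omitted.
#' @param samples Character vector of individuals (ignored when `gm`
#'   given).
#' @return List with `per_individual` (data.frame) and `stats`
#'   (data.frame measure x mean/sd/min/max).
#' @export
summarize_roh <- function(segments, gm = NULL, samples = NULL) {
  if (!is.null(gm)) samples <- rownames(gm$calls)
  if (is.null(samples)) stop("supply gm or samples")
  per <- data.frame(sample = samples, NSEG = 0, KB = 0, KB_AVER = 0,
                    NSNP = 0, density = 0, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    sp <- split(segments, factor(segments$sample, levels = samples))
    for (i in seq_along(samples)) {
      sg <- sp[[i]]
      if (is.null(sg) || !nrow(sg)) next
      kb <- sg$length_bp / 1000
      per$NSEG[i] <- nrow(sg)
      per$KB[i] <- sum(kb)
      per$KB_AVER[i] <- mean(kb)
      per$NSNP[i] <- mean(sg$n_snps)
      per$density[i] <- mean(kb / sg$n_snps)
    }
  }
  if (!is.null(gm)) {
    hom <- rowSums(gm$calls != 1L, na.rm = TRUE)
    called <- rowSums(!is.na(gm$calls))
    per$PHOM <- ifelse(called > 0, hom / called, NA)
  }
  meas <- setdiff(names(per), "sample")
  stats <- data.frame(
    measure = meas,
    mean = vapply(per[meas], mean, numeric(1)),
    sd = vapply(per[meas], stats::sd, numeric(1)),
    min = vapply(per[meas], min, numeric(1)),
    max = vapply(per[meas], max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_individual = per, stats = stats)
}

#' Permutation Kruskal-Wallis test between groups
#'
#' Compares a per-individual homozygosity measure (NSEG, KB, KB_AVER,
#' ...) between two or more groups using the Kruskal-Wallis rank
#' statistic with a label-permutation p-value.
#'
#' @param values Numeric vector of per-individual values.
#' @param groups Group labels (same length as `values`).
#' @param n_perm Number of label permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @return List with `statistic`, `p_value`, `n_per_group`, `n_perm`.
#' @export
compare_roh_groups <- function(values, groups, n_perm = 9999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 individuals per group")
  if (stats::sd(values) == 0)
    return(list(statistic = 0, p_value = 1,
                n_per_group = as.integer(table(groups)), n_perm = n_perm))
  kw_stat <- function(v)
    unname(stats::kruskal.test(v, groups)$statistic)
  obs <- kw_stat(values)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  perm <- replicate(n_perm, kw_stat(sample(values)))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  list(statistic = obs, p_value = p,
       n_per_group = as.integer(table(groups)), n_perm = n_perm)
}
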