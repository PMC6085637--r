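#' Weir-Cockerham FST between populations
#'
#' Per-locus variance components of the Weir & Cockerham (1984)
#' estimator for diploids: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals, from the
#' observed heterozygosity), with the multi-locus weighted estimate
#' `sum(a) / sum(a + b + c)`. Loci monomorphic across all populations,
#' or without calls in at least two populations, are skipped. Per-locus
#' estimates may legitimately be negative.
#'
#' @param ... Two or more `genotype_matrix` objects over the same
#'   variants (one per population), or a single list of them.
#' @return List of class `fst_result` with per-locus `a`, `b`, `c`,
#'   `fst_per_locus`, the `weighted` ratio-of-sums estimate, the
#'   unweighted `mean_per_locus`, and `n_loci_used`.
#' @export
weir_cockerham_fst <- function(...) {
  pops <- list(...)
  if (length(pops) == 1 && !inherits(pops[[1]], "genotype_matrix"))
    pops <- pops[[1]]
  r <- length(pops)
  if (r < 2) stop("need >= 2 populations")
  L <- n_variants(pops[[1]])
  if (!all(vapply(pops, n_variants, integer(1)) == L))
    stop("populations must share the same variant panel")
  ni <- sapply(pops, function(g) colSums(!is.na(g$calls)))       # L x r
  pi <- sapply(pops, function(g) {
    cc <- colSums(!is.na(g$calls))
    ifelse(cc > 0, colSums(g$calls, na.rm = TRUE) / (2 * cc), NA)
  })
  hi <- sapply(pops, function(g) {
    cc <- colSums(!is.na(g$calls))
    ifelse(cc > 0, colSums(g$calls == 1L, na.rm = TRUE) / cc, NA)
  })
  ni <- matrix(ni, nrow = L); pi <- matrix(pi, nrow = L); hi <- matrix(hi, nrow = L)
  ok <- rowSums(ni > 0) == r & rowSums(ni) > r   # calls in every pop
  nbar <- rowMeans(ni)
  pbar <- rowSums(ni * pi) / (r * nbar)
  ok <- ok & !is.na(pbar) & pbar > 0 & pbar < 1
  nc <- (r * nbar - rowSums(ni^2) / (r * nbar)) / (r - 1)
  s2 <- rowSums(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  tot <- a + b + cc
  per <- ifelse(tot != 0, a / tot, NA)
  structure(list(a = a, b = b, c = cc, fst_per_locus = per,
                 weighted = sum(a[ok]) / sum(tot[ok]),
                 mean_per_locus = mean(per[ok & !is.na(per)]),
                 n_loci_used = sum(ok)),
            class = "fst_result")
}

#' Pairwise weighted FST matrix
#'
#' @param subpops Named list of `genotype_matrix` objects on a shared
#'   panel.
#' @return Symmetric matrix of pairwise weighted FST values.
#' @export
fst_matrix <- function(subpops) {
  labs <- names(subpops)
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <-
      weir_cockerham_fst(subpops[[i]], subpops[[j]])$weighted
  }
  m
}

#' Nei's standard genetic distance
#'
#' Nei (1972) multi-locus distance `D = -ln I`, where the normalized
#' identity `I` accumulates numerator and denominators over loci before
#' the ratio: `I = sum(x y) / sqrt(sum(x^2) * sum(y^2))` with the sums
#' running over all alleles of all loci. For biallelic SNPs each locus
#' contributes its ref and alt allele frequencies.
#'
#' @param p1,p2 Alternate-allele frequency vectors over shared loci.
#' @return `D >= 0`; `Inf` when the populations share no alleles.
#' @export
nei_distance <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- sum(p1^2 + (1 - p1)^2)
  jy <- sum(p2^2 + (1 - p2)^2)
  I <- jxy / sqrt(jx * jy)
  if (I <= 0) return(Inf)
  -log(I)
}

#' Pairwise Nei distance matrix
#' @param subpops Named list of `genotype_matrix` objects on a shared
#'   panel.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
nei_matrix <- function(subpops) {
  freqs <- lapply(subpops, allele_freq)
  labs <- names(subpops)
  n <- length(labs)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    m[i, j] <- m[j, i] <- nei_distance(freqs[[i]], freqs[[j]])
  m
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix, with
#' negative branch lengths clamped to zero and the deficit moved to the
#' adjacent branch (so path lengths through the node are preserved where
#' possible), and newick serialization.
#'
#' @param dm Symmetric numeric matrix with zero diagonal and row/column
#'   labels.
#' @return List with `tree` (an `ape` `phylo`) and `newick` (character).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("need >= 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", seq_len(nrow(dm)))
  tr <- ape::nj(dm)
  # clamp negative branches, moving the deficit to the adjacent branch
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    node <- tr$edge[e, 1]
    adj <- setdiff(which(tr$edge[, 1] == node | tr$edge[, 2] == node), e)
    if (length(adj)) {
      a <- adj[1]
      tr$edge.length[a] <- max(0, tr$edge.length[a] + deficit)
    }
  }
  list(tree = tr, newick = ape::write.tree(tr))
}

#' Genotype principal component analysis
#'
#' Genotype codes are mean-imputed at missing calls, centered per SNP
#' (and optionally scaled by `sqrt(p(1-p))`), and decomposed; sample
#' coordinates on the top `k` components are returned with eigenvalue
#' fractions. The sign of each component is fixed so its
#' largest-magnitude SNP loading is positive.
#'
#' @param gm A `genotype_matrix`.
#' @param k Number of components (default 2).
#' @param scale Scale SNPs by `sqrt(p(1-p))`.
#' @return List with `coords` (samples x k), `explained` (length-k
#'   eigenvalue fractions over the full spectrum), `loadings`.
#' @export
genotype_pca <- function(gm, k = 2, scale = FALSE) {
  if (n_samples(gm) < 2) stop("need >= 2 samples")
  X <- gm$calls
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, mu)
  if (scale) {
    p <- mu / 2
    s <- sqrt(pmax(p * (1 - p), .Machine$double.eps))
    X <- sweep(X, 2, s, "/")
  }
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) stop("no variable SNPs")
  sv <- svd(X)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncating")
    k <- rank
  }
  ev <- sv$d^2
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  load <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    sgn <- sign(load[which.max(abs(load[, j])), j])
    if (sgn < 0) { load[, j] <- -load[, j]; coords[, j] <- -coords[, j] }
  }
  dimnames(coords) <- list(rownames(gm$calls), paste0("PC", seq_len(k)))
  list(coords = coords, explained = ev[seq_len(k)] / sum(ev),
       loadings = load)
}
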