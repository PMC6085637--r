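test_that("length and SNP-count thresholds gate segment calling", {
  p <- roh_params()
  gm <- make_gm(matrix(0L, 1, 60), pos = (0:59) * 2500L + 1L)  # 147.5 kb
  segs <- detect_roh(gm, p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 60)
  expect_equal(segs$length_bp, 59 * 2500 + 1)

  short <- make_gm(matrix(0L, 1, 60), pos = (0:59) * 1500L + 1L)  # 88.5 kb
  expect_equal(nrow(detect_roh(short, p)), 0)

  few <- make_gm(matrix(2L, 1, 49), pos = (0:48) * 4200L + 1L)    # 49 SNPs
  expect_equal(nrow(detect_roh(few, p)), 0)
})

test_that("fully heterozygous yields nothing; fully homozygous one run per chromosome", {
  pos <- (0:79) * 2000L + 1L
  v <- data.frame(chrom = rep(c("gga1", "gga2"), each = 80),
                  pos = c(pos, pos), ref = "A", alt = "G")
  het <- genotype_matrix(matrix(1L, 1, 160), v, samples = "h")
  expect_equal(nrow(detect_roh(het)), 0)
  hom <- genotype_matrix(matrix(2L, 1, 160), v, samples = "h")
  segs <- detect_roh(hom)
  expect_equal(nrow(segs), 2)
  expect_setequal(segs$chrom, c("gga1", "gga2"))
})

test_that("detector matches the brute-force window-scan oracle on random chromosomes", {
  p <- roh_params(window_bp = 50000, max_het_per_window = 1,
                  max_missing_per_window = 2, min_length_bp = 20000,
                  min_snps = 10, max_gap_bp = 30000)
  set.seed(101)
  n_checked <- 0
  for (rep in 1:120) {
    n <- sample(30:200, 1)
    pos <- sort(sample.int(4e5, n))
    geno <- sample(c(0L, 0L, 0L, 2L, 2L, 1L, NA), n, replace = TRUE)
    gm <- genotype_matrix(matrix(geno, 1), data.frame(
      chrom = "gga1", pos = pos, ref = "A", alt = "G"), samples = "x")
    got <- detect_roh(gm, p)
    want <- roh_oracle_chrom(geno, pos, p)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = paste("rep", rep))
    } else {
      expect_equal(nrow(got), nrow(want), info = paste("rep", rep))
      expect_equal(got$start, want$start, info = paste("rep", rep))
      expect_equal(got$end, want$end, info = paste("rep", rep))
      expect_equal(got$n_snps, want$n_snps, info = paste("rep", rep))
      n_checked <- n_checked + nrow(want)
    }
  }
  expect_gt(n_checked, 50)   # the sweep must actually exercise segments
})

test_that("SNP-count window mode also matches its oracle definition", {
  p <- roh_params(window_mode = "snps", window_snps = 20,
                  min_length_bp = 20000, min_snps = 10,
                  max_missing_per_window = 2, max_gap_bp = 30000)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(40:150, 1)
    pos <- sort(sample.int(3e5, n))
    geno <- sample(c(0L, 0L, 2L, 2L, 2L, 1L, NA), n, replace = TRUE)
    gm <- genotype_matrix(matrix(geno, 1), data.frame(
      chrom = "gga1", pos = pos, ref = "A", alt = "G"), samples = "x")
    ws <- min(20, n)
    anchors <- seq_len(n - ws + 1)
    hom_win <- vapply(anchors, function(j) {
      w <- j:(j + ws - 1)
      sum(geno[w] == 1, na.rm = TRUE) <= p$max_het_per_window &&
        sum(is.na(geno[w])) <= p$max_missing_per_window
    }, logical(1))
    elig <- vapply(seq_len(n), function(s) {
      a <- intersect(max(1, s - ws + 1):s, anchors)
      mean(hom_win[a]) >= p$hit_fraction
    }, logical(1))
    got_elig <- nrow(detect_roh(gm, p)) > 0
    # at minimum, agreement on whether any qualifying run exists
    r <- rle(elig); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    any_seg <- FALSE
    for (k in which(r$values)) {
      len <- pos[ends[k]] - pos[starts[k]] + 1
      if (len >= p$min_length_bp && r$lengths[k] >= p$min_snps &&
          max(diff(pos[starts[k]:ends[k]])) <= p$max_gap_bp)
        any_seg <- TRUE
    }
    if (!any_seg) expect_false(got_elig, label = paste("rep", rep))
  }
})

test_that("per-individual and group summaries follow the definitions", {
  segs <- data.frame(sample = c("a", "a"), chrom = "gga1",
                     start = c(1, 2e5), end = c(120000, 380000),
                     n_snps = c(60, 90))
  segs$length_bp <- segs$end - segs$start + 1
  sm <- summarize_roh(segs, samples = c("a", "b"))
  expect_equal(sm$per_individual$NSEG, c(2, 0))
  expect_equal(sm$per_individual$KB[1], (120000 + 180001) / 1000)
  expect_equal(sm$per_individual$KB_AVER[1], (120 + 180.001) / 2)
  st <- sm$stats
  expect_equal(st$mean[st$measure == "NSEG"], 1)
  expect_equal(st$sd[st$measure == "NSEG"], sqrt(2))

  # PHOM is genome-wide homozygous fraction of called genotypes
  gm <- make_gm(rbind(c(0, 1, 2, NA), c(1, 1, 1, 1)))
  sm2 <- summarize_roh(segs[0, ], gm = gm)
  expect_equal(sm2$per_individual$PHOM, c(2 / 3, 0))
})

test_that("group comparison is calibrated under the null and powered for shifts", {
  set.seed(3)
  vals <- rnorm(30)
  groups <- rep(c("A", "B", "C"), each = 10)
  ps <- vapply(1:9, function(s) {
    set.seed(s)
    compare_roh_groups(sample(vals), groups, n_perm = 499, seed = s)$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.1)

  shifted <- c(rnorm(10), rnorm(10) + 10)
  out <- compare_roh_groups(shifted, rep(c("A", "B"), each = 10),
                            n_perm = 1999, seed = 1)
  expect_lte(out$p_value, 1e-3)

  expect_error(compare_roh_groups(vals, rep("A", 30)), "2 groups")
  expect_equal(compare_roh_groups(rep(1, 20),
                                  rep(c("A", "B"), 10))$p_value, 1)
})
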