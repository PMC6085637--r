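test_that("perfect coupling gives r2 = 1 and equilibrium gives r2 near 0", {
  gm <- make_gm(cbind(c(0L, 0L, 2L, 2L), c(0L, 0L, 2L, 2L)),
                pos = c(100L, 200L))
  expect_equal(pairwise_r2(gm, 1, 2, "em"), 1, tolerance = 1e-9)
  expect_equal(pairwise_r2(gm, 1, 2, "composite"), 1, tolerance = 1e-12)

  eq <- hap_sample(2000, c(0.25, 0.25, 0.25, 0.25), seed = 4)
  gm2 <- make_gm(cbind(as.integer(eq$gA), as.integer(eq$gB)),
                 pos = c(100L, 200L))
  expect_lt(pairwise_r2(gm2, 1, 2, "em"), 0.01)
})

test_that("EM haplotype r2 matches the likelihood grid search to 1e-4", {
  cases <- list(
    list(n = 20, f = c(0.4, 0.1, 0.1, 0.4), seed = 1),
    list(n = 20, f = c(0.4, 0.1, 0.1, 0.4), seed = 2),
    list(n = 30, f = c(0.7, 0.1, 0.1, 0.1), seed = 3),
    list(n = 25, f = c(0.5, 0.3, 0.1, 0.1), seed = 4),
    list(n = 40, f = c(0.25, 0.25, 0.25, 0.25), seed = 5),
    list(n = 15, f = c(0.6, 0.05, 0.05, 0.3), seed = 6),
    list(n = 50, f = c(0.45, 0.05, 0.45, 0.05), seed = 7),
    list(n = 30, f = c(0.35, 0.3, 0.05, 0.3), seed = 8),
    list(n = 20, f = c(0.2, 0.4, 0.3, 0.1), seed = 9),
    list(n = 35, f = c(0.55, 0.15, 0.2, 0.1), seed = 10))
  tested <- 0
  for (cs in cases) {
    g <- hap_sample(cs$n, cs$f, cs$seed)
    if (var(g$gA) == 0 || var(g$gB) == 0) next
    gm <- make_gm(cbind(as.integer(g$gA), as.integer(g$gB)),
                  pos = c(100L, 200L))
    expect_equal(pairwise_r2(gm, 1, 2, "em"), grid_r2(g$gA, g$gB),
                 tolerance = 1e-4,
                 info = sprintf("case seed %d", cs$seed))
    tested <- tested + 1
  }
  expect_gte(tested, 10)
})

test_that("EM recovers the phase-known haplotype r2 when double hets are absent", {
  # without double heterozygotes every genotype pair resolves into
  # haplotypes uniquely; EM must land on the counted frequencies
  gA <- c(0L, 0L, 1L, 2L, 2L, 0L)
  gB <- c(0L, 0L, 0L, 2L, 1L, 0L)
  stopifnot(sum(gA == 1 & gB == 1) == 0)
  # direct haplotype tally: f(alt,alt) = 3/12, f(alt,ref) = 2/12
  f11 <- 3 / 12; pA <- 5 / 12; pB <- 3 / 12
  D <- f11 - pA * pB
  want <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  gm <- make_gm(cbind(gA, gB), pos = c(100L, 200L))
  expect_equal(pairwise_r2(gm, 1, 2, "em"), want, tolerance = 1e-8)

  # with homozygotes only, the composite estimator coincides too
  gm2 <- make_gm(cbind(c(0L, 0L, 2L, 2L, 2L, 0L), c(0L, 0L, 2L, 2L, 0L, 0L)),
                 pos = c(100L, 200L))
  expect_equal(pairwise_r2(gm2, 1, 2, "em"),
               pairwise_r2(gm2, 1, 2, "composite"), tolerance = 1e-8)
})

test_that("r2 is invariant to allele-label swaps at either locus", {
  g <- hap_sample(30, c(0.5, 0.2, 0.1, 0.2), seed = 12)
  for (m in c("em", "composite")) {
    base <- pairwise_r2(make_gm(cbind(g$gA, g$gB), pos = c(1L, 2L) * 100L),
                        1, 2, m)
    swapA <- pairwise_r2(make_gm(cbind(2L - g$gA, g$gB),
                                 pos = c(1L, 2L) * 100L), 1, 2, m)
    swapB <- pairwise_r2(make_gm(cbind(g$gA, 2L - g$gB),
                                 pos = c(1L, 2L) * 100L), 1, 2, m)
    expect_equal(base, swapA, tolerance = 1e-9)
    expect_equal(base, swapB, tolerance = 1e-9)
  }
  gm_mono <- make_gm(cbind(rep(1L, 6), rep(0L, 6)), pos = c(100L, 200L))
  expect_true(is.na(pairwise_r2(gm_mono, 1, 2, "composite")))
})

test_that("decay curve bins pairs by distance and interpolates the half maximum", {
  # constant r2: curve never decays -> infinite half-decay distance
  base <- rbinom(40, 2, 0.5)
  gm <- make_gm(matrix(rep(base, 6), ncol = 6),
                pos = as.integer(seq(1e4, 6e5, length.out = 6)))
  expect_warning(
    dc <- ld_decay(gm, max_distance_bp = 5e5, bins = 5, method = "composite"),
    "empty bin")
  expect_true(is.infinite(dc$half_decay_bp))

  # single usable bin: undefined
  gm2 <- make_gm(matrix(rep(base, 2), ncol = 2), pos = c(1000L, 2000L))
  dc2 <- suppressWarnings(ld_decay(gm2, max_distance_bp = 5e5, bins = 5,
                                   method = "composite"))
  expect_true(is.na(dc2$half_decay_bp))

  # constructed decay: r2 = 1 nearby, ~0 at long range
  set.seed(8)
  far <- rbinom(40, 2, 0.5)
  codes <- cbind(base, base, far, rbinom(40, 2, 0.5))
  gm3 <- make_gm(codes, pos = c(1e4L, 6e4L, 35e4L, 48e4L))
  dc3 <- suppressWarnings(ld_decay(gm3, max_distance_bp = 5e5, bins = 5,
                                   method = "composite"))
  expect_lt(dc3$half_decay_bp, 3e5)
  expect_equal(sum(dc3$bins$n_pairs), 6)
})

test_that("Waples bias correction and Ne inversion behave at the landmarks", {
  # in the no-correction limit r2' = 1/(3 Ne) inverts to ~ Ne
  r2p <- 1 / (3 * 100)
  ne <- (1 / 3 + sqrt(1 / 9 - 2.76 * r2p)) / (2 * r2p)
  expect_equal(ne, 100, tolerance = 0.12)   # quadratic term shifts it slightly
  w <- consgen:::waples_ne(r2p + 1 / 50 + 3.19 / 50^2, S = 50)
  expect_equal(w$r2_prime, r2p, tolerance = 1e-12)
  expect_equal(w$ne, ne, tolerance = 1e-9)
  # non-positive corrected r2 flags infinite Ne
  expect_true(is.infinite(consgen:::waples_ne(1 / 60, S = 60)$ne))
})

test_that("per-chromosome Ne estimates average within karyotype classes", {
  set.seed(15)
  v <- NULL; codes <- NULL
  for (ch in c("gga2", "gga7", "gga12")) {
    codes <- cbind(codes, sapply(runif(30, 0.2, 0.8),
                                 function(q) rbinom(40, 2, q)))
    v <- rbind(v, data.frame(chrom = ch, pos = seq_len(30) * 1000L,
                             ref = "A", alt = "G"))
  }
  gm <- genotype_matrix(codes, v, samples = paste0("s", 1:40))
  ne <- ne_from_ld(gm)
  expect_setequal(ne$per_chromosome$class, c("macro", "intermediate", "micro"))
  fin <- ne$per_chromosome[is.finite(ne$per_chromosome$ne), ]
  if (nrow(fin) == 3)
    expect_equal(unname(ne$class_averages["overall"]), mean(fin$ne))
  expect_error(ne_from_ld(gm[1:5, ]), ">= 10")
})
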