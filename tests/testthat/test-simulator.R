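test_that("zero generations returns founders only, all non-inbred", {
  cfg <- sim_config(Nm = 3, Nf = 6, n_generations = 0, scheme = "RF",
                    sample_plan = data.frame(generation = 0, n_males = 2,
                                             n_females = 3),
                    genome = sim_genome(n_chrom = 1, n_snps = 30,
                                        length_bp = 1e6),
                    seed = 1)
  sim <- simulate_flock(cfg)
  expect_equal(nrow(sim$pedigree), 9)
  expect_true(all(is.na(sim$pedigree$sire)))
  expect_equal(unname(pedigree_inbreeding(sim$pedigree)), rep(0, 9))
  expect_equal(n_samples(sim$samples$gen0), 5)
})

test_that("RF retention keeps one son per sire family and one daughter per dam", {
  cfg <- sim_config(Nm = 5, Nf = 5, n_generations = 3, scheme = "RF",
                    seed = 3, genotypes = FALSE)
  sim <- simulate_flock(cfg)
  ped <- sim$pedigree
  for (g in 1:3) {
    gen <- ped[ped$generation == g, ]
    # every sire of the previous generation fathers exactly one retained son
    expect_equal(sort(as.integer(table(gen$sire[gen$sex == "M"]))), rep(1L, 5))
    expect_equal(sort(as.integer(table(gen$dam[gen$sex == "F"]))), rep(1L, 5))
  }
})

test_that("pedigree integrity: parents always come from the previous generation", {
  for (scheme in c("RR", "RF", "FR")) {
    cfg <- sim_config(Nm = 4, Nf = 8, n_generations = 4, scheme = scheme,
                      seed = 11, genotypes = FALSE)
    ped <- simulate_flock(cfg)$pedigree
    kids <- ped[!is.na(ped$sire), ]
    gen_of <- setNames(ped$generation, ped$id)
    expect_true(all(gen_of[as.character(kids$sire)] == kids$generation - 1))
    expect_true(all(gen_of[as.character(kids$dam)] == kids$generation - 1))
    expect_true(all(ped$sex[match(kids$sire, ped$id)] == "M"))
    expect_true(all(ped$sex[match(kids$dam, ped$id)] == "F"))
  }
})

test_that("identical seeds reproduce the simulation bit-for-bit", {
  cfg <- sim_config(Nm = 3, Nf = 6, n_generations = 2, scheme = "RF",
                    genome = sim_genome(n_chrom = 2, n_snps = 40,
                                        length_bp = 1e6),
                    sample_plan = data.frame(generation = 2, n_males = 2,
                                             n_females = 2),
                    seed = 99)
  s1 <- simulate_flock(cfg)
  s2 <- simulate_flock(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$samples$gen2$calls, s2$samples$gen2$calls)
})

test_that("allele-frequency drift is unbiased and its variance grows", {
  set.seed(42)
  d1 <- c(); d4 <- c()
  for (rep in 1:12) {
    cfg <- sim_config(Nm = 5, Nf = 10, n_generations = 4, scheme = "RR",
                      genome = sim_genome(n_chrom = 1, n_snps = 120,
                                          length_bp = 5e6),
                      sample_plan = data.frame(generation = c(0, 1, 4),
                                               n_males = 5, n_females = 10),
                      seed = 1000 + rep)
    sim <- simulate_flock(cfg)
    p0 <- allele_freq(sim$samples$gen0)
    d1 <- c(d1, allele_freq(sim$samples$gen1) - p0)
    d4 <- c(d4, allele_freq(sim$samples$gen4) - p0)
  }
  expect_lt(abs(mean(d1)), 0.01)
  expect_lt(abs(mean(d4)), 0.02)
  expect_gt(var(d4), var(d1))
})

test_that("within-family replacement slows inbreeding relative to random selection", {
  f_rf <- c(); f_rr <- c()
  for (rep in 1:10) {
    for (scheme in c("RF", "RR")) {
      cfg <- sim_config(Nm = 4, Nf = 16, n_generations = 8, scheme = scheme,
                        seed = 500 + rep, genotypes = FALSE)
      mf <- mean_inbreeding_by_generation(simulate_flock(cfg)$pedigree)
      val <- mf$mean_F[mf$generation == 8]
      if (scheme == "RF") f_rf <- c(f_rf, val) else f_rr <- c(f_rr, val)
    }
  }
  expect_lt(mean(f_rf), mean(f_rr))
})

test_that("heterozygosity declines in step with realized pedigree inbreeding", {
  he0 <- c(); he_t <- c(); f_t <- c()
  for (rep in 1:6) {
    cfg <- sim_config(Nm = 4, Nf = 12, n_generations = 6, scheme = "RF",
                      genome = sim_genome(n_chrom = 2, n_snps = 150,
                                          length_bp = 1e7),
                      sample_plan = data.frame(generation = c(0, 6),
                                               n_males = 4, n_females = 12),
                      seed = 7000 + rep)
    sim <- simulate_flock(cfg)
    he0 <- c(he0, expected_heterozygosity(sim$samples$gen0))
    he_t <- c(he_t, expected_heterozygosity(sim$samples$gen6))
    mf <- mean_inbreeding_by_generation(sim$pedigree)
    f_t <- c(f_t, mf$mean_F[mf$generation == 6])
  }
  retention <- mean(he_t) / mean(he0)
  expect_equal(retention, 1 - mean(f_t), tolerance = 0.05)
})

test_that("the study fixture has the designed census and determinism", {
  fx <- generate_study_fixture(seed = 5,
                               genome = sim_genome(n_chrom = 2, n_snps = 60,
                                                   length_bp = 5e6),
                               generations = c(1, 2, 3))
  expect_length(fx$subpops, 9)
  expect_true(all(vapply(fx$subpops, n_samples, integer(1)) == 30))
  expect_equal(nrow(fx$map), 270)
  expect_equal(as.integer(table(fx$map$sex)), c(180L, 90L)) # 20 F + 10 M per pool
  fx2 <- generate_study_fixture(seed = 5,
                                genome = sim_genome(n_chrom = 2, n_snps = 60,
                                                    length_bp = 5e6),
                                generations = c(1, 2, 3))
  expect_identical(fx$subpops[[1]]$calls, fx2$subpops[[1]]$calls)
  expect_identical(fx$map, fx2$map)
})
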