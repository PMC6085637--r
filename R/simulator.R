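#' Default simulated genome
#'
#' Five macro-like autosomes, desk-scale: each carries `n_snps` evenly
#' dense SNPs on a `length_bp` chromosome at a chicken-like recombination
#' rate of 3 cM/Mb.
#'
#' @param n_chrom Number of chromosomes.
#' @param length_bp Chromosome length.
#' @param n_snps SNPs per chromosome.
#' @param cM_per_Mb Recombination rate.
#' @return `data.frame` with one row per chromosome.
#' @export
sim_genome <- function(n_chrom = 5, length_bp = 2e7, n_snps = 1000,
                       cM_per_Mb = 3) {
  data.frame(chrom = paste0("gga", seq_len(n_chrom)),
             length_bp = length_bp, n_snps = n_snps,
             cM_per_Mb = cM_per_Mb, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Describes a closed conserved flock: breeding census, number of
#' discrete generations, replacement scheme, genome map, founder allele
#' frequency spectrum and sampling plan.
#'
#' Schemes: `"RR"` — random selection, random mating (replacements drawn
#' uniformly from the offspring pool); `"RF"` — random mating within
#' families with exactly one son retained per sire family and one
#' daughter per dam family; `"FR"` — family rotation: dam families are
#' fixed, each dam is replaced by her own daughter, and the replacement
#' sire of family i is a son born in family i-1 (mod Nm).
#'
#' @param Nm,Nf Breeding sires / dams per generation (`Nm <= Nf`).
#' @param n_generations Number of discrete generations to simulate.
#' @param scheme `"RR"`, `"RF"` or `"FR"`.
#' @param genome `data.frame` as from [sim_genome()].
#' @param founder_maf_range Founder alternate-allele frequencies are
#'   drawn uniformly from this range (default `[0.05, 0.5]`).
#' @param sample_plan Optional `data.frame` with columns `generation`,
#'   `n_males`, `n_females`: breeders to export as genotype samples.
#' @param seed Mandatory RNG seed.
#' @param genotypes Simulate genotypes (set `FALSE` for pedigree-only
#'   runs, which are much faster).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(Nm, Nf, n_generations, scheme = c("RF", "RR", "FR"),
                       genome = sim_genome(), founder_maf_range = c(0.05, 0.5),
                       sample_plan = NULL, seed, genotypes = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(Nm >= 1, Nf >= Nm, n_generations >= 0, !missing(seed))
  if (scheme %in% c("RF", "FR") && Nf %% Nm != 0)
    stop("RF/FR schemes require Nf divisible by Nm (even family sizes)")
  structure(list(Nm = Nm, Nf = Nf, n_generations = n_generations,
                 scheme = scheme, genome = genome,
                 founder_maf_range = founder_maf_range,
                 sample_plan = sample_plan, seed = seed,
                 genotypes = genotypes),
            class = "sim_config")
}

# One meiosis: recombine the two parental haplotypes (rows of H) into a
# gamete, chromosome by chromosome. chr_idx/chr_pos/chr_len/chr_cM are
# per-chromosome lists/vectors.
make_gamete <- function(H, parent_rows, chr_idx, chr_pos, chr_len_bp, chr_cM) {
  g <- integer(ncol(H))
  for (c in seq_along(chr_idx)) {
    idx <- chr_idx[[c]]
    k <- stats::rpois(1, chr_cM[c] / 100)
    start <- sample.int(2, 1)
    if (k == 0) {
      g[idx] <- H[parent_rows[start], idx]
    } else {
      bp <- sort(stats::runif(k, 0, chr_len_bp[c]))
      seg <- findInterval(chr_pos[[c]], bp)
      hap <- (start - 1 + seg) %% 2 + 1
      g[idx] <- ifelse(hap == 1, H[parent_rows[1], idx], H[parent_rows[2], idx])
    }
  }
  g
}

#' Forward-in-time simulation of a conservation mating scheme
#'
#' Simulates a closed flock of `Nm` sires and `Nf` dams over discrete,
#' non-overlapping generations. Founders are drawn in linkage
#' equilibrium from the configured allele-frequency spectrum; each
#' generation dams are partitioned evenly (and at random) among sires
#' into families, gametes are formed with Poisson crossovers (no
#' interference, no mutation), and replacements are selected per the
#' scheme (see [sim_config()]). The full pedigree is tracked.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `pedigree` (`data.frame`: `id`, `sire`, `dam`,
#'   `sex`, `generation`), `samples` (named list of `genotype_matrix`
#'   objects, one per sampled generation, `NULL` entries when
#'   `genotypes = FALSE`), and `final_ids` (breeder ids of the last
#'   generation).
#' @export
simulate_flock <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  Nm <- cfg$Nm; Nf <- cfg$Nf; N <- Nm + Nf
  gen <- cfg$genome
  L <- sum(gen$n_snps)
  chr_idx <- split(seq_len(L), rep(seq_len(nrow(gen)), gen$n_snps))
  chr_pos <- lapply(seq_len(nrow(gen)), function(c)
    sort(sample.int(gen$length_bp[c], gen$n_snps[c])))
  variants <- data.frame(
    chrom = rep(gen$chrom, gen$n_snps),
    pos = unlist(chr_pos),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  chr_cM <- gen$length_bp / 1e6 * gen$cM_per_Mb
  do_geno <- isTRUE(cfg$genotypes)

  founder_p <- stats::runif(L, cfg$founder_maf_range[1], cfg$founder_maf_range[2])
  H <- NULL
  if (do_geno) {
    H <- matrix(stats::rbinom(2 * N * L, 1, rep(founder_p, each = 2 * N)),
                nrow = 2 * N, ncol = L)
    storage.mode(H) <- "integer"
  }
  # breeders of the current generation: males 1..Nm, females Nm+1..N
  ped <- list(data.frame(id = seq_len(N), sire = NA_integer_,
                         dam = NA_integer_,
                         sex = rep(c("M", "F"), c(Nm, Nf)),
                         generation = 0L, stringsAsFactors = FALSE))
  cur_ids <- seq_len(N)
  next_id <- N + 1L
  samples <- list()
  grab_sample <- function(g, H, ids) {
    sp <- cfg$sample_plan
    if (is.null(sp) || !g %in% sp$generation) return(NULL)
    row <- sp[sp$generation == g, ][1, ]
    m_ids <- ids[seq_len(Nm)]; f_ids <- ids[Nm + seq_len(Nf)]
    pick <- c(sample(m_ids, row$n_males), sample(f_ids, row$n_females))
    sex <- rep(c("M", "F"), c(row$n_males, row$n_females))
    if (!do_geno)
      return(list(ids = pick, sex = sex, gm = NULL))
    rows1 <- 2 * match(pick, ids) - 1L
    calls <- H[rows1, , drop = FALSE] + H[rows1 + 1L, , drop = FALSE]
    gm <- genotype_matrix(calls, variants, samples = paste0("ind", pick))
    attr(gm, "sex") <- sex
    list(ids = pick, sex = sex, gm = gm)
  }
  s0 <- grab_sample(0L, H, cur_ids)
  if (!is.null(s0)) samples[["gen0"]] <- s0

  fam_fixed <- rep(seq_len(Nm), length.out = Nf)  # FR: dam slots keep families
  for (g in seq_len(cfg$n_generations)) {
    fam_of_dam <- if (cfg$scheme == "FR") fam_fixed
                  else sample(rep(seq_len(Nm), length.out = Nf))
    # choose matings per scheme; each row: sire slot, dam slot, sex
    if (cfg$scheme == "RF") {
      son_dam <- vapply(seq_len(Nm), function(s)
        sample(which(fam_of_dam == s), 1), integer(1))
      mat <- data.frame(sire_slot = c(seq_len(Nm), fam_of_dam),
                        dam_slot = c(son_dam, seq_len(Nf)),
                        sex = rep(c("M", "F"), c(Nm, Nf)))
    } else if (cfg$scheme == "RR") {
      dam_m <- sample.int(Nf, Nm, replace = TRUE)
      dam_f <- sample.int(Nf, Nf, replace = TRUE)
      mat <- data.frame(sire_slot = c(fam_of_dam[dam_m], fam_of_dam[dam_f]),
                        dam_slot = c(dam_m, dam_f),
                        sex = rep(c("M", "F"), c(Nm, Nf)))
    } else { # FR: sire of family i comes from family i-1; dams self-replace
      son_fam <- (seq_len(Nm) - 2L) %% Nm + 1L   # family supplying sire i
      son_dam <- vapply(son_fam, function(s)
        sample(which(fam_of_dam == s), 1), integer(1))
      mat <- data.frame(sire_slot = c(son_fam, fam_of_dam),
                        dam_slot = c(son_dam, seq_len(Nf)),
                        sex = rep(c("M", "F"), c(Nm, Nf)))
    }
    sire_ids <- cur_ids[mat$sire_slot]
    dam_ids <- cur_ids[Nm + mat$dam_slot]
    new_ids <- next_id:(next_id + N - 1L)
    next_id <- next_id + N
    ped[[g + 1L]] <- data.frame(id = new_ids, sire = sire_ids, dam = dam_ids,
                                sex = mat$sex, generation = g,
                                stringsAsFactors = FALSE)
    if (do_geno) {
      Hn <- matrix(0L, nrow = 2 * N, ncol = L)
      for (o in seq_len(N)) {
        srow <- 2 * mat$sire_slot[o] - 1L
        drow <- 2 * (Nm + mat$dam_slot[o]) - 1L
        Hn[2 * o - 1L, ] <- make_gamete(H, c(srow, srow + 1L),
                                        chr_idx, chr_pos, gen$length_bp, chr_cM)
        Hn[2 * o, ] <- make_gamete(H, c(drow, drow + 1L),
                                   chr_idx, chr_pos, gen$length_bp, chr_cM)
      }
      H <- Hn
    }
    cur_ids <- new_ids
    sg <- grab_sample(g, H, cur_ids)
    if (!is.null(sg)) samples[[paste0("gen", g)]] <- sg
  }
  pedigree <- do.call(rbind, ped)
  gms <- lapply(samples, `[[`, "gm")
  list(pedigree = pedigree, samples = gms,
       sample_info = lapply(samples, function(s) s[c("ids", "sex")]),
       final_ids = cur_ids)
}

#' Mean pedigree inbreeding per generation
#'
#' Fast kinship recursion for discrete-generation pedigrees (parents
#' always one generation back, as produced by [simulate_flock()]):
#' tracks the kinship matrix of each generation's breeders and reads
#' each individual's inbreeding coefficient as the kinship of its
#' parents.
#'
#' @param ped Pedigree `data.frame` with columns `id`, `sire`, `dam`,
#'   `generation`.
#' @return `data.frame` with columns `generation`, `mean_F`.
#' @export
mean_inbreeding_by_generation <- function(ped) {
  gens <- sort(unique(ped$generation))
  prev <- ped[ped$generation == gens[1], ]
  K <- diag(0.5, nrow(prev))
  out <- data.frame(generation = gens[1], mean_F = 0)
  for (g in gens[-1]) {
    cur <- ped[ped$generation == g, ]
    s <- match(cur$sire, prev$id)
    d <- match(cur$dam, prev$id)
    if (anyNA(s) || anyNA(d))
      stop("parents not all in previous generation; use pedigree_inbreeding")
    Fv <- K[cbind(s, d)]
    n <- nrow(cur)
    A <- matrix(0, n, nrow(prev))
    A[cbind(seq_len(n), s)] <- A[cbind(seq_len(n), s)] + 0.5
    A[cbind(seq_len(n), d)] <- A[cbind(seq_len(n), d)] + 0.5
    Kn <- A %*% K %*% t(A)
    diag(Kn) <- 0.5 * (1 + Fv)
    out <- rbind(out, data.frame(generation = g, mean_F = mean(Fv)))
    K <- Kn
    prev <- cur
  }
  out
}

#' Generate the nine-subpopulation study fixture
#'
#' Three independently founded breeds simulated under the within-family
#' replacement scheme (RF) with 30 sires and 300 dams, each sampled at
#' generations 9, 12 and 17 (10 males + 20 females per sample), on a
#' desk-scale panel of 5,000 SNPs over 5 chromosomes — a synthetic
#' miniature of a three-breed, three-generation conservation monitoring
#' design. Deterministic for a fixed seed.
#'
#' @param seed RNG seed.
#' @param genome Genome map (default [sim_genome()]).
#' @param generations Sampled generations (default `c(9, 12, 17)`).
#' @return List with `subpops` (named list of nine `genotype_matrix`),
#'   `map` (`data.frame`: `sample`, `subpop`, `sex`), `plans` (named
#'   list of [mating_plan()] per breed), `pedigrees` (per breed).
#' @export
generate_study_fixture <- function(seed, genome = sim_genome(),
                                   generations = c(9, 12, 17)) {
  breeds <- c("B1", "B2", "B3")
  sp <- data.frame(generation = generations, n_males = 10, n_females = 20)
  subpops <- list(); map <- list(); peds <- list()
  for (b in seq_along(breeds)) {
    cfg <- sim_config(Nm = 30, Nf = 300, n_generations = max(generations),
                      scheme = "RF", genome = genome, sample_plan = sp,
                      seed = seed + 1000L * b)
    sim <- simulate_flock(cfg)
    peds[[breeds[b]]] <- sim$pedigree
    for (g in generations) {
      gm <- sim$samples[[paste0("gen", g)]]
      lab <- sprintf("%s_t%02d", breeds[b], g)
      rownames(gm$calls) <- paste0(lab, "_", seq_len(nrow(gm$calls)))
      subpops[[lab]] <- gm
      map[[lab]] <- data.frame(sample = rownames(gm$calls), subpop = lab,
                               sex = attr(gm, "sex"),
                               stringsAsFactors = FALSE)
    }
  }
  plans <- stats::setNames(
    rep(list(mating_plan(30, 300, start_year = 1998)), 3), breeds)
  list(subpops = subpops, map = do.call(rbind, c(map, make.row.names = FALSE)),
       plans = plans, pedigrees = peds)
}
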