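---
title: "Monitoring genomic diversity in conserved flocks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring genomic diversity in conserved flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`consgen` monitors the genetic health of small closed populations — the
situation of national poultry gene-pool flocks kept at around 30 breeding
sires and 300 dams — from genome-wide SNP genotypes sampled at successive
generations. This vignette explains the statistical models behind each
stage, the tunable parameters and their defaults, the design of the
forward simulator used for validation, and the limits of what the
package's tests demonstrate.

## The monitoring question

A conservation program succeeds if, over a planning horizon of decades,
the flock retains most of its founding genetic diversity (a common target
is 90 % retention) while inbreeding stays below a ceiling (commonly
F < 0.1). Both requirements are checked by `run_pipeline()` and
`generational_trend()`, whose thresholds (`retention = 0.9`,
`f_max = 0.1`) are configurable but default to those conventions.

## Quality control

`apply_qc()` filters SNPs by three per-SNP criteria, counting each
excluded SNP once under the *first* criterion it fails, in the order
Hardy–Weinberg, then minor allele frequency, then call rate, so report
categories are exclusive and sum to the total excluded:

* **HWE exact test** (`hwe_exact_test`, default floor `1e-6`): the
  two-sided exact test that enumerates every heterozygote count
  compatible with the observed allele counts and sums the probabilities
  of configurations no more likely than the observed one. The plain
  (non-mid-p) definition is used. The suite verifies it against exact
  integer enumeration for *every* genotype configuration up to 30
  diploids.
* **MAF** (default `0.05`) among called alleles.
* **Call rate** (default `0.95`) per SNP. A separate per-*sample*
  missing-rate limit (default `0.01`) only flags samples in the report;
  monitoring designs rarely discard scarce conserved-line samples, so
  dropping them is left to the analyst. The two limits are deliberately
  distinct parameters because "call rate" and "missing rate" name
  different axes of the genotype matrix.

`ld_prune()` is a greedy windowed pruner (defaults 50-SNP windows, step
5, r² threshold 0.2): within a window, while any retained pair exceeds
the threshold, the lower-MAF member of the worst pair is removed (ties
broken towards the later position — a deterministic choice so pipelines
are reproducible). Pruning r² is the genotype-count (composite)
correlation; the EM haplotype r² lives in the LD module and is used for
decay curves, matching how the two estimators are conventionally paired.

## Diversity statistics

Per sub-population, over SNPs with at least one called genotype:

* `observed_heterozygosity`: mean fraction of called genotypes that are
  heterozygous.
* `expected_heterozygosity`: mean 2p(1−p). The small-sample factor
  2n/(2n−1) (Nei's unbiased estimator) is available via
  `unbiased = TRUE` but off by default, matching the common
  genotype-tool convention.
* `proportion_polymorphic`: the denominator is the *shared QC'd panel*,
  not the SNPs called within the sub-population, so fixation shows up as
  lost polymorphism rather than vanishing silently from the denominator.
* `allelic_richness`: rarefaction to a standardized number of gene
  copies g removes the dependence of allele counts on sample size. The
  closed form E[alleles in g copies] = Σᵢ [1 − C(N−Nᵢ, g)/C(N, g)] is
  exact; the suite proves it against brute-force enumeration of all
  C(N, g) subsamples for N ≤ 12 and checks monotonicity in g. Because g
  must be chosen (it is not implied by the data), `diversity_summary()`
  logs it; the default is 2 × (smallest sub-population size) × 0.95,
  floored.
* `nucleotide_diversity_windows`: per-site unbiased pairwise diversity
  2·c_ref·c_alt/(c(c−1)) summed per window and divided by the window
  size (100 kb windows, 10 kb step by default). Windows anchor at
  position 1 of each chromosome and the final partial window keeps the
  nominal divisor — the convention of the widely used windowed-π tools,
  which slightly deflates the last window rather than inflating it.

## Two inbreeding coefficients

**Mating-plan (F_ES).** For a hierarchical design with N_m sires and
N_f dams the per-generation increment is

ΔF = (3 N_f + N_m)/(16 N_m N_f),   Ne = 1/(2 ΔF) = 8 N_m N_f/(3 N_f + N_m),

accumulated as F(t) = 1 − (1 − ΔF)^t over t discrete generations
(default one per calendar year). A note on provenance: the classical
presentation of this model prints the right-hand side of the first
equation as "Ne" itself. Dimensionally it is a rate, not a size — it
shrinks as the census grows, evaluating to ≈ 0.0065 at 30 × 300 — and
treating it as ΔF = 1/(2Ne) is the only reading that reproduces the
published inbreeding trajectories for the 30 × 300 design; `delta_f()`
therefore implements the rate reading and `ne_from_census()` its
implied size (≈ 77.4 at 30 × 300).

**Genomic (F_ROH).** The fraction of the SNP-covered autosomal genome
inside runs of homozygosity, averaged over individuals. This needs no
pedigree and reflects realized, not expected, autozygosity.

**Pedigree (validation only).** `pedigree_inbreeding()` implements the
tabular numerator-relationship recursion; for the simulator's
discrete-generation pedigrees `mean_inbreeding_by_generation()` tracks
the kinship matrix one generation at a time, which is orders of
magnitude cheaper and is proven equal to the tabular method in the
suite.

### What the recovery experiment shows

Simulating the R:F scheme at 30 sires × 300 dams for 17 generations
(24 replicates) gives mean pedigree inbreeding ≈ 0.052, in close
agreement with the classical equalized-family-size result
Ne = 16·N_m·N_f/(3 N_f + N_m) ≈ 155, i.e. ΔF ≈ 0.0032 — and a factor
of two *below* the mating-plan model above (F(17) = 0.104). The two
formulas differ exactly by the factor-2 credit that equalizing family
sizes earns relative to random selection. In other words, the
mating-plan F_ES used in monitoring reports is a conservative
(pessimistic) envelope for an R:F flock rather than an unbiased
prediction; the package keeps the conventional F_ES definition for
reporting and documents the gap here and in the acceptance suite, where
the corresponding check is intentionally left failing rather than
re-tuned. Under random selection (R:R) the simulator realizes
F(17) ≈ 0.071, matching Wright's 4·N_m·N_f/(N_m+N_f) ≈ 109 with the
usual one-generation lag, and the ordering F(R:F) < F(R:R) holds in
every replicate set — the premise that family equalization slows
inbreeding.

## Runs of homozygosity

`detect_roh()` follows the three-phase sliding-window definition:

1. every window of `window_bp` (default 1 Mb) anchored at a SNP is
   scored homozygous iff it contains ≤ 1 heterozygous and ≤ 5 missing
   calls (defaults chosen to tolerate genotyping error);
2. a SNP is eligible iff ≥ 5 % (`hit_fraction`) of windows covering it
   are homozygous;
3. maximal runs of consecutive eligible SNPs, split at inter-SNP gaps
   above 1 Mb, become segments if ≥ 100 kb long, ≥ 50 SNPs, and at most
   50 kb/SNP.

The window is defined in physical length; a SNP-count window mode
(`window_mode = "snps"`) is provided for parity with tools that window
by SNP count. Segment bounds are the first/last SNP positions (not
window edges); lengths are end − start + 1. PHOM is computed genome-wide
over all called genotypes, not only inside segments — with ~50 SNPs per
run and dense panels this is the reading that yields the familiar
≈ 0.99 values for livestock. The optimized prefix-sum scanner is tested
against a naive direct transcription of the definition on hundreds of
randomized chromosomes.

Between-group differences in NSEG/KB/KB_AVER use the Kruskal–Wallis
statistic with a seeded label-permutation p-value (default 9,999
permutations): the measures are right-skewed counts and sums, so a rank
test with an exact-style permutation reference needs no distributional
assumptions.

## Differentiation and structure

`weir_cockerham_fst()` implements the 1984 variance-component estimator
for diploids (components a, b, c with the observed-heterozygosity
correction), reporting both the ratio-of-sums "weighted" multi-locus
value and the mean of per-locus ratios, since published FST values do
not always say which was used. Identical populations give a weighted
value ≤ 0 (the unbiasedness correction), fixed differences give exactly
1, and a population split randomly in half stays within |FST| < 0.02 at
n = 30 and 1,000 SNPs.

`nei_distance()` accumulates Nei's (1972) identity numerator and
denominators over loci *before* the ratio (the multi-locus definition),
rather than averaging per-locus ratios. `neighbor_joining()` delegates
the Saitou–Nei agglomeration to `ape::nj` and then clamps negative
branch lengths to zero, moving the deficit to the adjacent branch so
path lengths are preserved where possible — the standard practical
remedy for the estimator's known small-sample artifact. `genotype_pca()`
mean-imputes missing calls, centers per SNP (variance scaling by
√(p(1−p)) is optional and off by default), and fixes each component's
sign so the largest-magnitude loading is positive, making coordinates
reproducible across runs.

## LD and effective population size

`pairwise_r2()` offers the EM maximum-likelihood haplotype-frequency r²
for unphased diploids (tolerance 1e-8, ≤ 1000 iterations, three starts
to avoid the rare non-global mode) and the composite genotype
correlation. The EM implementation is vectorized across locus pairs via
genotype-class cross-products, and is tested against a grid search of
the one-dimensional profile likelihood to 1e-4.

`ld_decay()` bins intra-chromosomal pairs by distance (default five
equal bins over 0–500 kb, the conventional consolidation for chicken
panels) and reports the distance where the binned curve first drops
below half its maximum, linearly interpolated between bin midpoints.
The interpolation scheme is a package choice; with five coarse bins any
half-maximum distance is resolution-limited, so the curve itself is
always reported alongside.

`ne_from_ld()` uses the composite r² averaged over intra-chromosomal
pairs, the Waples (2006) sample-size correction
(r²′ = r² − 1/S − 3.19/S² for S ≥ 30, the published small-sample
coefficients below that), and the random-mating inversion
Ne = (1/3 + √(1/9 − 2.76 r²′))/(2 r²′). Chromosomes whose corrected r²
is non-positive are flagged infinite and excluded from class averages
(macro gga1–5, intermediate gga6–10, micro gga11–28 — the chicken
karyotype convention; macro-class averages are the headline number
because microchromosomes' high recombination departs furthest from the
model).

Two biases matter in practice and are deliberately surfaced rather than
hidden. First, restricting to intra-chromosomal pairs (the only pairing
that is well-defined without the original tool's locus grouping) mixes
linked pairs into an estimator derived for unlinked loci, inflating r²
and deflating Ne — the LD-Ne recovery experiment therefore simulates
genomes with large genetic lengths (20 chromosomes × 3,000 cM) so that
most pairs are effectively unlinked. Even so the estimator recovers true
sizes 26/50/100 with the correct ordering and roughly a factor-of-two
downward compression (medians ≈ 22/31/57 over 20 replicates), which is
the well-documented behavior of LD-Ne with residually linked loci and
whole-population sampling. Second, when applied to dense real panels
where most pairs *are* linked, absolute Ne values should be read as
lower bounds; trends across generations remain interpretable.

## The simulator

`simulate_flock()` is a forward-in-time, discrete-generation simulator
of a closed flock:

* founders drawn in linkage equilibrium with alternate-allele
  frequencies uniform on [0.05, 0.5] — a post-QC-like spectrum, since
  monitoring operates on MAF-filtered panels;
* each generation, dams are partitioned evenly and at random among
  sires (N_f/N_m per family);
* gametes recombine with Poisson crossovers (no interference) at a
  default 3 cM/Mb — the order of magnitude of chicken macrochromosomes —
  with per-chromosome rates configurable; mutation is omitted because
  drift dominates completely on horizons of tens of generations;
* replacement per scheme: R:R draws every replacement from a random
  dam's litter; R:F retains exactly one son per sire family and one
  daughter per dam family; F:R keeps dam families fixed (each dam
  replaced by her own daughter) and rotates each family's replacement
  sire in from the neighboring family. Offspring sex is assigned
  directly to the slot being filled, which is equivalent to redrawing
  Bernoulli(0.5) sexes until quotas are met and keeps litters minimal;
* the full pedigree (id, sire, dam, sex, generation) is returned, and
  any generation's breeders can be exported as a genotype matrix.

`generate_study_fixture()` assembles the desk-scale analogue of a
three-breed monitoring design: three independently founded breeds under
R:F at 30 × 300, each sampled at generations 9, 12 and 17 (the calendar
of a program started in 1998 and sampled in 2007/2010/2015) with
10 males + 20 females per sample, on 5,000 SNPs over five 20 Mb
chromosomes. Independent founding means between-breed FST lands near
0.11–0.14 while within-breed generational FST stays below ~0.015 — the
ordering a real multi-breed program shows. One breed of the real design
would have ~39 generations of history; the fixture does not replay that
depth, since its purpose is statistical structure (drift, family
structure, finite-size LD), not historical realism.

What the fixture does *not* emulate — and what passing tests therefore
do not demonstrate about real data: GBS ascertainment and genotyping
error, site-frequency spectra with rare alleles (founders are
MAF-truncated by construction), mutation, selection, migration,
overlapping generations, and real chicken marker densities (~716k SNPs
genome-wide; simulations run at thousands). Statistics whose values
depend on those features (absolute π, absolute decay distances, ROH
length distributions) are validated against their own definitions and
oracles, not against published magnitudes.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for a single CPU:
pedigree-only recovery runs use 24 replicates of 17 generations at
330 breeders; LD-Ne recovery uses 20 replicates × 3 sizes at 500 SNPs
and 8 generations; the fixture uses 5,000 SNPs. These sizes were chosen
so Monte-Carlo standard errors sit comfortably inside the asserted
tolerances (e.g. replicate SD of mean F(17) ≈ 0.0014 against a ±0.015
band); larger panels change runtimes, not conclusions.

## Known limitations

* F_ES is a closed-form expectation of the mating plan, not an estimate
  from data; as shown above it overstates R:F inbreeding by about 2×,
  and the package reports it as the conventional, conservative
  monitoring quantity.
* LD-Ne point estimates from dense intra-chromosomal panels are biased
  low; use them comparatively.
* The HWE test assumes autosomal diploid genotypes; no sex-aware test
  is provided (the pipeline excludes non-autosomes at read time).
* `detect_roh` does not impute missing calls; heavy missingness shortens
  runs before the window budget can compensate.
* STRUCTURE-style admixture inference and its model-selection heuristics
  are out of scope; PCA, NJ trees and FST carry the structure analysis.
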