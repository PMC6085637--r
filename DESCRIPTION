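Package: consgen
Title: Genomic Diversity Monitoring for Conserved Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to monitor genomic diversity across generations of small
    conserved populations from genome-wide SNP genotypes. Implements SNP
    quality control (call rate, minor allele frequency, Hardy-Weinberg exact
    test) and windowed LD pruning; per-subpopulation diversity statistics
    (observed and expected heterozygosity, proportion of polymorphic
    markers, rarefaction allelic richness, windowed nucleotide diversity);
    mating-plan and runs-of-homozygosity inbreeding coefficients; Weir and
    Cockerham's FST, Nei's standard genetic distance, neighbor-joining
    trees and genotype PCA; LD decay curves and LD-based effective
    population size with chromosome-class averaging; and a forward-in-time
    simulator of conservation mating schemes (random, within-family, and
    rotational replacement) with pedigree tracking, used to generate
    synthetic study fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
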