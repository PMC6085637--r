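# Small in-code fixtures shared across test files.

# Genotype matrix from a samples x variants code matrix on one chromosome,
# positions 1 kb apart unless given.
make_gm <- function(codes, pos = NULL, chrom = "gga1") {
  codes <- as.matrix(codes)
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 1000L
  genotype_matrix(codes,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                             stringsAsFactors = FALSE),
                  samples = paste0("s", seq_len(nrow(codes))))
}

# Random genotype matrix with given missingness, seeded.
random_gm <- function(n, m, miss = 0, seed = 1, chrom = "gga1") {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  codes <- sapply(p, function(q) rbinom(n, 2, q))
  if (miss > 0) codes[runif(n * m) < miss] <- NA
  make_gm(matrix(codes, nrow = n), chrom = chrom)
}

# Write a small VCF text file, returning its path.
write_test_vcf <- function(records, samples, dir = tempdir()) {
  path <- tempfile("test", fileext = ".vcf", tmpdir = dir)
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts)
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
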