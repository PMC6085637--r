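#' Read genotypes from a VCF file
#'
#' Reads the GT field of a VCF 4.x file into a [genotype_matrix()].
#' Only biallelic SNP records are accepted: multi-allelic records and
#' indels are skipped and counted. Phase separators (`|`) are read but
#' ignored; all downstream statistics treat genotypes as unphased.
#'
#' @param path Path to a (plain-text or bgzipped) VCF file.
#' @param karyotype Character vector of accepted chromosome labels
#'   (default [gga_autosomes()]); records on other contigs are skipped
#'   with a warning, or cause an error when `strict = TRUE`. Use `NULL`
#'   to accept every contig.
#' @param strict Error (rather than warn) on unknown chromosomes.
#' @param verbose Print a summary of skipped records.
#' @return A `genotype_matrix` with attribute `skipped`, a named integer
#'   vector counting records dropped as `non_biallelic` or `off_karyotype`.
#' @export
read_vcf <- function(path, karyotype = gga_autosomes(), strict = FALSE,
                     verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no records in VCF: ", path)
  alt <- fix$ALT
  ref <- fix$REF
  snp <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  onk <- if (is.null(karyotype)) rep(TRUE, nrow(fix)) else fix$CHROM %in% karyotype
  if (strict && any(!onk))
    stop("records on chromosomes outside the declared karyotype: ",
         paste(unique(fix$CHROM[!onk]), collapse = ", "))
  keep <- snp & onk
  skipped <- c(non_biallelic = sum(!snp), off_karyotype = sum(snp & !onk))
  if (verbose && sum(skipped))
    message("read_vcf: skipped ", skipped[["non_biallelic"]],
            " non-biallelic/indel and ", skipped[["off_karyotype"]],
            " off-karyotype records")
  if (!is.null(karyotype) && any(!onk) && !strict)
    warning(sum(snp & !onk), " record(s) on unknown chromosomes skipped")
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  # map GT strings to alt-allele dosage; "." or ./. -> NA
  code <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1", "1")] <- 2L
    out
  }
  calls <- t(apply(gt, 1, code))
  calls <- matrix(as.integer(calls), nrow = nrow(gt), ncol = ncol(gt))
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = ref[keep], alt = alt[keep],
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(t(calls), variants, samples = colnames(gt))
  attr(gm, "skipped") <- skipped
  gm
}

#' Write genotypes to a minimal VCF file
#'
#' Emits a plain-text VCF 4.2 file carrying only the GT field, suitable
#' for re-reading with [read_vcf()] or external tools.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$calls)), collapse = "\t")),
             con)
  gtstr <- c("0/0", "0/1", "1/1")
  m <- matrix("./.", nrow = ncol(gm$calls), ncol = nrow(gm$calls))
  ok <- !is.na(t(gm$calls))
  m[ok] <- gtstr[t(gm$calls)[ok] + 1L]
  v <- gm$variants
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(m, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read/write the tabular genotype dialect
#'
#' A plain TSV mirror of the genotype matrix: a header row
#' `chrom pos ref alt <sample1> <sample2> ...`, then one row per variant
#' with genotype codes 0/1/2 and `.` for missing. Round-trips bit-exactly
#' through [write_geno_tsv()] / [read_geno_tsv()].
#'
#' @param path File path.
#' @return `read_geno_tsv`: a `genotype_matrix`.
#' @export
read_geno_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype TSV needs a header and >= 1 variant row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (length(hdr) < 5 || !identical(hdr[1:4], c("chrom", "pos", "ref", "alt")))
    stop("header must start with: chrom pos ref alt")
  samples <- hdr[-(1:4)]
  ncol_exp <- length(hdr)
  nlen <- lengths(fields[-1])
  if (any(nlen != ncol_exp))
    stop("ragged row(s) at line ", paste(which(nlen != ncol_exp) + 1L, collapse = ", "))
  body <- do.call(rbind, fields[-1])
  codes <- body[, -(1:4), drop = FALSE]
  codes[codes == "."] <- NA
  calls <- matrix(as.integer(codes), nrow = nrow(body))
  variants <- data.frame(chrom = body[, 1], pos = as.integer(body[, 2]),
                         ref = body[, 3], alt = body[, 4],
                         stringsAsFactors = FALSE)
  genotype_matrix(t(calls), variants, samples = samples)
}

#' @rdname read_geno_tsv
#' @param gm A `genotype_matrix`.
#' @return `write_geno_tsv`: `path`, invisibly.
#' @export
write_geno_tsv <- function(gm, path) {
  v <- gm$variants
  codes <- t(gm$calls)
  codes[is.na(codes)] <- "."
  lines <- c(paste(c("chrom", "pos", "ref", "alt", rownames(gm$calls)),
                   collapse = "\t"),
             paste(v$chrom, v$pos, v$ref, v$alt,
                   apply(codes, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sub-population map
#'
#' Two-column TSV `sample subpop` with an optional third column
#' `sex` (M/F). No header.
#'
#' @param path File path.
#' @return `data.frame` with columns `sample`, `subpop` and (if present)
#'   `sex`.
#' @export
read_subpop_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("sub-population map needs >= 2 columns")
  names(tab)[1:2] <- c("sample", "subpop")
  if (ncol(tab) >= 3) {
    names(tab)[3] <- "sex"
    if (!all(tab$sex %in% c("M", "F")))
      stop("sex column must be M or F")
  }
  tab
}

#' @rdname read_subpop_map
#' @param map `data.frame` with columns `sample`, `subpop`, optional `sex`.
#' @export
write_subpop_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
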