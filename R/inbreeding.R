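#' Mating-plan description
#'
#' The census of a closed conserved flock: number of breeding sires and
#' dams per generation, the year conservation started, and the number of
#' discrete generations per calendar year.
#'
#' @param Nm Breeding males per generation.
#' @param Nf Breeding females per generation.
#' @param start_year Conservation initial year.
#' @param generations_per_year Generation turnover rate (default 1).
#' @return A list of class `mating_plan`.
#' @export
mating_plan <- function(Nm, Nf, start_year, generations_per_year = 1) {
  stopifnot(Nm >= 1, Nf >= 1, generations_per_year > 0)
  structure(list(Nm = Nm, Nf = Nf, start_year = start_year,
                 generations_per_year = generations_per_year),
            class = "mating_plan")
}

#' Per-generation inbreeding increment from the mating census
#'
#' Evaluates `(3 Nf + Nm) / (16 Nm Nf)`, the rate at which inbreeding
#' accumulates under the hierarchical sire/dam mating model. Interpreted
#' as `1/(2 Ne)`, this corresponds to an effective population size
#' `Ne = 8 Nm Nf / (3 Nf + Nm)`. Note that the source model's published
#' form prints this quantity as "Ne" itself; dimensionally it is a rate,
#' and only the rate reading reproduces the accumulated coefficients the
#' model is calibrated against (see the methods vignette).
#'
#' @param Nm,Nf Breeding males / females per generation.
#' @return The increment (delta F) per generation.
#' @export
delta_f <- function(Nm, Nf) {
  if (Nm < 1 || Nf < 1) stop("Nm and Nf must be >= 1")
  (3 * Nf + Nm) / (16 * Nm * Nf)
}

#' Effective population size implied by the mating census
#' @inheritParams delta_f
#' @return `Ne = 8 Nm Nf / (3 Nf + Nm)` (so that delta F = 1/(2 Ne)).
#' @export
ne_from_census <- function(Nm, Nf) 1 / (2 * delta_f(Nm, Nf))

#' Mating-plan (expected) inbreeding coefficient
#'
#' Accumulates the per-generation increment over the generations elapsed
#' between the conservation start and the sampling year:
#' `F = 1 - (1 - delta F)^t` with
#' `t = (sampling_year - start_year) * generations_per_year`.
#'
#' @param plan A [mating_plan()].
#' @param sampling_year Calendar year of sampling (`>= start_year`).
#' @param digits Decimals for the reported value (default 4, matching
#'   conventional report precision); use `NA` for full precision.
#' @return F_ES in `[0, 1)`.
#' @export
f_es <- function(plan, sampling_year, digits = 4) {
  stopifnot(inherits(plan, "mating_plan"))
  t <- (sampling_year - plan$start_year) * plan$generations_per_year
  if (any(t < 0)) stop("sampling_year before start_year")
  dF <- delta_f(plan$Nm, plan$Nf)
  out <- 1 - (1 - dF)^t
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' ROH-based inbreeding coefficient
#'
#' Fraction of the SNP-covered autosomal genome lying inside runs of
#' homozygosity, per individual, and its mean over individuals.
#'
#' @param segments `data.frame` of ROH segments with columns `sample`,
#'   `chrom`, `start`, `end` (bp, inclusive), as from [detect_roh()].
#'   Segments must be non-overlapping within an individual.
#' @param genome_length_bp Total autosomal length covered by the SNP map.
#' @param samples Character vector of all individuals (so individuals
#'   with no segments contribute 0); defaults to those present in
#'   `segments`.
#' @return List with `per_individual` (named numeric) and `mean`.
#' @export
f_roh <- function(segments, genome_length_bp, samples = NULL) {
  stopifnot(genome_length_bp > 0)
  if (is.null(samples)) samples <- unique(segments$sample)
  per <- stats::setNames(numeric(length(samples)), samples)
  if (nrow(segments)) {
    for (grp in split(segments, paste(segments$sample, segments$chrom))) {
      o <- order(grp$start)
      if (any(grp$start[o][-1] <= grp$end[o][-nrow(grp)]))
        stop("overlapping ROH segments for sample ", grp$sample[1],
             " on ", grp$chrom[1], "; merge before calling f_roh")
    }
    len <- tapply(segments$end - segments$start + 1, segments$sample, sum)
    per[names(len)] <- len / genome_length_bp
  }
  list(per_individual = per, mean = mean(per))
}

#' Pedigree inbreeding coefficients
#'
#' Inbreeding via the tabular numerator-relationship method:
#' `F(x) = kinship(sire(x), dam(x))`, founders taken as non-inbred and
#' unrelated. Individuals are processed in an order where parents precede
#' offspring; a cycle makes such an order impossible and raises an error.
#'
#' @param ped `data.frame` with columns `id`, `sire`, `dam` (parent ids,
#'   `NA` for unknown/founder).
#' @return Named numeric vector of inbreeding coefficients, one per `id`.
#' @export
pedigree_inbreeding <- function(ped) {
  ped <- as.data.frame(ped, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  si <- match(as.character(ped$sire), id)
  di <- match(as.character(ped$dam), id)
  # topological order: repeatedly place individuals whose parents are placed
  placed <- logical(n); ord <- integer(n); k <- 0L
  parent_ok <- function(p) is.na(p) | placed[replace(p, is.na(p), 1L)]
  repeat {
    ready <- !placed & parent_ok(si) & parent_ok(di)
    if (!any(ready)) break
    idx <- which(ready)
    ord[k + seq_along(idx)] <- idx
    k <- k + length(idx)
    placed[idx] <- TRUE
  }
  if (k < n) stop("pedigree contains a cycle")
  A <- matrix(0, n, n)
  Fv <- numeric(n)
  for (i in ord) {
    s <- si[i]; d <- di[i]
    if (!is.na(s) && !is.na(d)) {
      Fv[i] <- 0.5 * A[s, d]
      A[i, ] <- 0.5 * (A[s, ] + A[d, ])
    } else if (!is.na(s)) {
      A[i, ] <- 0.5 * A[s, ]
    } else if (!is.na(d)) {
      A[i, ] <- 0.5 * A[d, ]
    }
    A[, i] <- A[i, ]
    A[i, i] <- 1 + Fv[i]
  }
  stats::setNames(Fv, id)
}

#' Squared correlation between two inbreeding coefficient series
#'
#' Squared Pearson correlation between mating-plan (F_ES) and genomic
#' (F_ROH) inbreeding coefficients over sub-populations, the summary used
#' to judge whether the pedigree-free genomic coefficient tracks the
#' mating-plan expectation.
#'
#' @param f_es_values,f_roh_values Numeric vectors (same length, >= 3).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   series has zero variance.
#' @export
fes_froh_correlation <- function(f_es_values, f_roh_values) {
  stopifnot(length(f_es_values) == length(f_roh_values))
  if (length(f_es_values) < 3) stop("need >= 3 records")
  if (stats::sd(f_es_values) == 0 || stats::sd(f_roh_values) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(f_es_values, f_roh_values)^2
}
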