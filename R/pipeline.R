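# TSV writer with provenance header lines (prefixed '#').
write_tsv_prov <- function(df, path, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# consgen ",
                      as.character(utils::packageVersion("consgen"))),
               paste0("# ", extra)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full diversity-monitoring pipeline
#'
#' Orchestrates QC, LD pruning, per-subpopulation diversity statistics,
#' mating-plan and ROH inbreeding, pairwise FST, Nei distance +
#' neighbor-joining tree, PCA, LD decay and LD-Ne, and generational
#' trend flags, writing one file per result into `out_dir`. Every output
#' carries a provenance header (package version, seed, parameters). A
#' `MANIFEST` file lists the completed stages; on failure the stages
#' completed so far are still listed.
#'
#' @param gm A `genotype_matrix` with all samples.
#' @param map Sub-population map (`sample`, `subpop`, optional `sex`).
#' @param plans Named list of [mating_plan()] per breed (optional).
#' @param years `data.frame` with columns `subpop`, `breed`,
#'   `year` assigning each sub-population its breed and sampling year
#'   (required when `plans` given).
#' @param out_dir Output directory (created if needed).
#' @param thresholds [qc_thresholds()].
#' @param prune [prune_params()].
#' @param roh [roh_params()].
#' @param seed Seed recorded in outputs and used for any stochastic
#'   stage.
#' @param ld_method r-squared estimator for the decay curve.
#' @param retention,f_max Conservation flags: minimum fraction of
#'   first-generation diversity retained, maximum inbreeding.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(gm, map, plans = NULL, years = NULL,
                         out_dir, thresholds = qc_thresholds(),
                         prune = prune_params(), roh = roh_params(),
                         seed = 1, ld_method = "composite",
                         retention = 0.9, f_max = 0.1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  prov <- sprintf("seed=%d", seed)
  res <- list()
  finish <- function() writeLines(done, file.path(out_dir, "MANIFEST"))
  on.exit(finish())

  qc <- apply_qc(gm, thresholds)
  jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  done <- c(done, "qc")
  res$qc <- qc$report

  keep <- ld_prune(qc$gm, prune)
  pruned <- qc$gm[, keep]
  writeLines(paste(pruned$variants$chrom, pruned$variants$pos, sep = ":"),
             file.path(out_dir, "pruned_variants.txt"))
  done <- c(done, "prune")

  subs_p <- split_by_subpopulation(pruned, map)   # pruned: diversity/structure
  subs_q <- split_by_subpopulation(qc$gm, map)    # unpruned QC: ROH/LD/FST

  div <- diversity_summary(subs_p)
  res$diversity <- div

  froh_mean <- numeric(0)
  roh_stats <- list()
  genome_len <- sum(tapply(qc$gm$variants$pos, qc$gm$variants$chrom,
                           function(p) max(p) - min(p) + 1))
  for (lab in names(subs_q)) {
    segs <- detect_roh(subs_q[[lab]], roh)
    sm <- summarize_roh(segs, gm = subs_q[[lab]])
    roh_stats[[lab]] <- cbind(subpop = lab, sm$stats)
    fr <- f_roh(segs, genome_len, samples = rownames(subs_q[[lab]]$calls))
    froh_mean[lab] <- fr$mean
  }
  write_tsv_prov(do.call(rbind, roh_stats), file.path(out_dir, "roh_summary.tsv"),
                 c(prov, sprintf("window_bp=%g min_length_bp=%g min_snps=%d",
                                 roh$window_bp, roh$min_length_bp, roh$min_snps)))
  done <- c(done, "roh")
  res$f_roh <- froh_mean

  fes_col <- rep(NA_real_, nrow(div))
  if (!is.null(plans)) {
    stopifnot(!is.null(years))
    for (i in seq_len(nrow(div))) {
      y <- years[years$subpop == div$subpop[i], ]
      if (nrow(y)) fes_col[i] <- f_es(plans[[y$breed[1]]], y$year[1])
    }
  }
  div_out <- cbind(div, F_ES = fes_col, F_ROH = froh_mean[div$subpop])
  write_tsv_prov(div_out, file.path(out_dir, "diversity.tsv"),
                 c(prov, sprintf("richness_g=%d", attr(div, "richness_g"))))
  done <- c(done, "diversity")
  res$table <- div_out
  if (sum(!is.na(fes_col)) >= 3)
    res$fes_froh_r2 <- fes_froh_correlation(fes_col[!is.na(fes_col)],
                                            froh_mean[div$subpop][!is.na(fes_col)])

  fst <- fst_matrix(subs_q)
  write_tsv_prov(as.data.frame(fst), file.path(out_dir, "fst_matrix.tsv"), prov)
  done <- c(done, "fst")
  res$fst <- fst

  nj <- neighbor_joining(nei_matrix(subs_p))
  writeLines(nj$newick, file.path(out_dir, "nj_tree.nwk"))
  done <- c(done, "nj")
  res$tree <- nj

  pca <- genotype_pca(pruned, k = 2)
  pca_df <- data.frame(sample = rownames(pca$coords), pca$coords)
  write_tsv_prov(pca_df, file.path(out_dir, "pca.tsv"),
                 c(prov, paste0("explained=",
                                paste(signif(pca$explained, 4), collapse = ","))))
  done <- c(done, "pca")
  res$pca <- pca

  ld_rows <- list(); ne_rows <- list()
  for (lab in names(subs_q)) {
    dc <- ld_decay(subs_q[[lab]], method = ld_method)
    ld_rows[[lab]] <- cbind(subpop = lab, dc$bins,
                            half_decay_bp = dc$half_decay_bp)
    ne <- ne_from_ld(subs_q[[lab]])
    ne_rows[[lab]] <- data.frame(subpop = lab,
                                 t(ne$class_averages))
  }
  write_tsv_prov(do.call(rbind, c(ld_rows, make.row.names = FALSE)),
                 file.path(out_dir, "ld_decay.tsv"), prov)
  write_tsv_prov(do.call(rbind, c(ne_rows, make.row.names = FALSE)),
                 file.path(out_dir, "ne_estimates.tsv"), prov)
  done <- c(done, "ld_ne")
  res$ne <- do.call(rbind, c(ne_rows, make.row.names = FALSE))

  if (!is.null(years)) {
    flags <- list()
    for (b in unique(years$breed)) {
      labs <- years$subpop[years$breed == b]
      rows <- div[match(labs, div$subpop), ]
      if (nrow(rows) >= 2) {
        fv <- c(fes_col[match(labs, div$subpop)], froh_mean[labs])
        tr <- generational_trend(rows, f_values = fv[!is.na(fv)],
                                 retention = retention, f_max = f_max)
        flags[[b]] <- data.frame(breed = b, retention_ok = tr$retention_ok,
                                 inbreeding_ok = tr$inbreeding_ok)
      }
    }
    if (length(flags))
      write_tsv_prov(do.call(rbind, flags), file.path(out_dir, "trend_flags.tsv"),
                     c(prov, sprintf("retention=%.2f f_max=%.2f", retention, f_max)))
    done <- c(done, "trends")
    res$flags <- if (length(flags)) do.call(rbind, flags) else NULL
  }
  invisible(res)
}
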