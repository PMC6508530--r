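#' Construct a qPCR Ct table
#'
#' Long-format quantification-cycle (Ct) measurements. Each row is one well:
#' a target locus or gene, a biological sample, that sample's genotype
#' group, the assay template, a technical replicate index and the Ct value.
#' Technical replicates are averaged on the Ct scale before any delta-Ct
#' computation.
#'
#' @param df data.frame with columns `target`, `sample_id`, `genotype`,
#'   `assay` (one of `mnase`, `gdna`, `cdna`), `tech_rep`, `ct` (> 0)
#' @return object of class `ct_table` (a data.frame)
#' @export
ct_table <- function(df) {
  cols <- c("target", "sample_id", "genotype", "assay", "tech_rep", "ct")
  if (!all(cols %in% names(df)))
    stop("ct table is missing columns: ", paste(setdiff(cols, names(df)), collapse = ", "))
  df <- as.data.frame(df)[cols]
  for (cc in c("target", "sample_id", "genotype", "assay"))
    df[[cc]] <- as.character(df[[cc]])
  if (!all(df$assay %in% c("mnase", "gdna", "cdna")))
    stop("assay must be one of mnase, gdna, cdna")
  if (any(!is.finite(df$ct) | df$ct <= 0)) stop("Ct values must be positive")
  class(df) <- c("ct_table", "data.frame")
  df
}

# mean Ct over technical replicates for one (target, assay), per sample;
# errors if a sample lacks the assay
mean_ct <- function(ct, target, assay, samples) {
  keep <- ct$target == target & ct$assay == assay
  if (!any(keep))
    stop("no '", assay, "' assay measurements for target '", target, "'")
  m <- tapply(ct$ct[keep], ct$sample_id[keep], mean)
  miss <- setdiff(samples, names(m))
  if (length(miss))
    stop("missing '", assay, "' assay for target '", target, "' in sample(s): ",
         paste(miss, collapse = ", "))
  m[samples]
}

#' MNase-qPCR relative nucleosome protection
#'
#' Quantifies nucleosome protection at a target locus by comparing
#' MNase-digested template to undigested genomic DNA:
#' `rNP(target) = 2^-(Ct_mnase - Ct_gdna)` per sample, normalized to a
#' control locus with a genotype-invariant nucleosome position (default
#' `Mwp1`): the reported value is `rNP(target) / rNP(control)`. Genotype
#' groups are summarized as mean +/- SD on the fold-change scale and
#' compared with a two-sided pooled Student t-test when exactly two groups
#' are present.
#'
#' @param ct a [ct_table()] with `mnase` and `gdna` assays for both loci
#' @param target target locus name
#' @param control_locus normalization locus (default `"Mwp1"`)
#' @param log_scale if `TRUE`, group summaries (mean, SD, t-test) are
#'   computed on the log2 fold-change scale
#' @return object of class `qpcr_np`: list with `samples` (per-sample
#'   data.frame: `sample_id`, `genotype`, `dct_target`, `dct_control`,
#'   `relative_np`), `groups` (mean, sd, n per genotype), `t_test`
#'   (statistic, p, df; `NULL` unless exactly 2 groups), `target`,
#'   `control_locus`.
#' @export
relative_np <- function(ct, target, control_locus = "Mwp1", log_scale = FALSE) {
  stopifnot(inherits(ct, "ct_table"))
  samples <- unique(ct$sample_id[ct$target %in% c(target, control_locus)])
  d_t <- mean_ct(ct, target, "mnase", samples) - mean_ct(ct, target, "gdna", samples)
  d_c <- mean_ct(ct, control_locus, "mnase", samples) -
    mean_ct(ct, control_locus, "gdna", samples)
  rnp <- 2^(-d_t) / 2^(-d_c)
  geno <- ct$genotype[match(samples, ct$sample_id)]
  per_sample <- data.frame(sample_id = samples, genotype = geno,
                           dct_target = as.numeric(d_t),
                           dct_control = as.numeric(d_c),
                           relative_np = as.numeric(rnp),
                           stringsAsFactors = FALSE)
  structure(c(group_summary(per_sample, "relative_np", log_scale),
              list(samples = per_sample, target = target,
                   control_locus = control_locus)),
            class = "qpcr_np")
}

#' qRT-PCR relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' dCt of the calibrator genotype group; the fold change is `2^-ddCt`, so
#' the calibrator group's mean ddCt is 0 and its geometric mean fold change
#' is exactly 1 by construction (the non-mutant gene in the wild genotype
#' is set to 1). Group summaries and a
#' two-sided pooled t-test as in [relative_np()]. The formulas assume an
#' amplification efficiency of 2 (perfect per-cycle doubling).
#'
#' @param ct a [ct_table()] with `cdna` assays for both genes
#' @param target target gene
#' @param reference_gene internal-control gene measured in every sample
#'   (e.g. a ubiquitin-conjugating enzyme gene or 45S rRNA)
#' @param calibrator_genotype genotype group whose mean is set to 1
#' @param log_scale summaries on the log2 scale if `TRUE`
#' @return object of class `qpcr_expression`: list with `samples`
#'   (`sample_id`, `genotype`, `dct`, `ddct`, `fold`), `groups`, `t_test`,
#'   `target`, `reference_gene`, `calibrator_genotype`.
#' @export
relative_expression <- function(ct, target, reference_gene, calibrator_genotype,
                                log_scale = FALSE) {
  stopifnot(inherits(ct, "ct_table"))
  samples <- unique(ct$sample_id[ct$target %in% c(target, reference_gene)])
  dct <- mean_ct(ct, target, "cdna", samples) -
    mean_ct(ct, reference_gene, "cdna", samples)
  geno <- ct$genotype[match(samples, ct$sample_id)]
  if (!any(geno == calibrator_genotype))
    stop("calibrator group '", calibrator_genotype, "' has no samples")
  ddct <- dct - mean(dct[geno == calibrator_genotype])
  per_sample <- data.frame(sample_id = samples, genotype = geno,
                           dct = as.numeric(dct), ddct = as.numeric(ddct),
                           fold = as.numeric(2^(-ddct)),
                           stringsAsFactors = FALSE)
  structure(c(group_summary(per_sample, "fold", log_scale),
              list(samples = per_sample, target = target,
                   reference_gene = reference_gene,
                   calibrator_genotype = calibrator_genotype)),
            class = "qpcr_expression")
}

# group means/SDs and pooled t-test between exactly two genotype groups
group_summary <- function(per_sample, value_col, log_scale) {
  v <- per_sample[[value_col]]
  if (log_scale) v <- log2(v)
  g <- per_sample$genotype
  groups <- data.frame(genotype = unique(g),
                       n = as.integer(tapply(v, g, length)[unique(g)]),
                       mean = as.numeric(tapply(v, g, mean)[unique(g)]),
                       sd = as.numeric(tapply(v, g, stats::sd)[unique(g)]),
                       stringsAsFactors = FALSE)
  tt <- NULL
  if (length(unique(g)) == 2L) {
    gs <- unique(g)
    res <- probe_ttest(v[g == gs[1]], v[g == gs[2]])
    tt <- list(group_a = gs[1], group_b = gs[2], t = res$t, p = res$p,
               df = res$df, scale = if (log_scale) "log2" else "fold")
  }
  list(groups = groups, t_test = tt)
}

#' @export
print.qpcr_np <- function(x, ...) {
  cat(sprintf("MNase-qPCR relative nucleosome protection at %s (normalized to %s)\n",
              x$target, x$control_locus))
  print.data.frame(x$groups, digits = 3)
  if (!is.null(x$t_test))
    cat(sprintf("  %s vs %s: t = %.3f, p = %.4g\n", x$t_test$group_a,
                x$t_test$group_b, x$t_test$t, x$t_test$p))
  invisible(x)
}

#' @export
print.qpcr_expression <- function(x, ...) {
  cat(sprintf("Relative expression of %s (2^-ddCt, reference %s, calibrator %s)\n",
              x$target, x$reference_gene, x$calibrator_genotype))
  print.data.frame(x$groups, digits = 3)
  if (!is.null(x$t_test))
    cat(sprintf("  %s vs %s: t = %.3f, p = %.4g\n", x$t_test$group_a,
                x$t_test$group_b, x$t_test$t, x$t_test$p))
  invisible(x)
}

#' Read / write a Ct table as CSV
#' @param path file path
#' @param ct a [ct_table()]
#' @return `read_ct_csv` returns a `ct_table`; `write_ct_csv` returns `ct`
#'   invisibly.
#' @export
read_ct_csv <- function(path) {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ct_csv
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(ct)
}
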