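#' Default pipeline configuration
#'
#' All tunable parameters of [run_pipeline()] with their defaults: the
#' synthetic experiment at study scale, per-probe `alpha = 0.05`, window
#' retention `min_fraction = 0.5`, run `min_span = 140` bp, `max_gap` = the
#' layout step, NOL `flank = 0` and `tie_epsilon = 1e-9`, truth-scoring
#' `overlap_rule = 0.5`. Any element can be overridden; unknown names are
#' an error.
#'
#' @param ... overrides, e.g. `np_config(n_windows = 40, seed = 7)`
#' @return named list of parameters
#' @export
np_config <- function(...) {
  cfg <- list(
    n_windows = 400L, span = 3000L, probe_length = 50L, step = 50L,
    genotypes = c(wild_type = "ref", mutant = "alt"), n_replicates = 3L,
    n_changes = 50L, change_kinds = c("gain", "loss"), delta = 1.0,
    change_width = 200L, n_polymorphic = 40L, polymorphism_effect = 2.0,
    noise_sd = 0.2, nol_distortion = 0,
    alpha = 0.05, min_fraction = 0.5, min_span = 140L, max_gap = NULL,
    flank = 0, tie_epsilon = 1e-9, overlap_rule = 0.5,
    qpcr_protection_ratio = 0.5, qpcr_expression_fold = 0.5,
    qpcr_noise_sd = 0.1, seed = 1L, outdir = NULL)
  ov <- list(...)
  if (length(ov) == 1L && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [np_config()] parameters
#' @return named list of parameters (defaults filled in)
#' @export
read_np_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genotypes)) y$genotypes <- unlist(y$genotypes)
  np_config(y)
}

#' Run the full differential nucleosome-position pipeline
#'
#' Simulates a synthetic experiment (or accepts one), then runs the stages
#' in order: polymorphism filter on the reference channels, differential NP
#' calling on the masked windows, NOL classification of each call, MNase-
#' qPCR and qRT-PCR quantification on simulated Ct tables, and scoring of
#' the calls against the planted truth. If `config$outdir` is set, all
#' stage outputs (signal GFFs, mask JSON, calls TSV, verdict TSV, Ct CSVs,
#' report JSON) are written there. The run is fully determined by
#' `config$seed`.
#'
#' @param config a list from [np_config()] / [read_np_config()]
#' @param experiment optionally, a pre-built `np_experiment` to analyze
#'   instead of simulating one from `config`
#' @return object of class `np_report`: list with `config`, `mask` counts,
#'   `calls`, `verdicts`, `qpcr`, `score` and the underlying objects
#' @export
run_pipeline <- function(config = np_config(), experiment = NULL) {
  config <- np_config(config)
  if (is.null(experiment)) {
    experiment <- simulate_experiment(
      n_windows = config$n_windows, span = config$span,
      probe_length = config$probe_length, step = config$step,
      genotypes = config$genotypes, n_replicates = config$n_replicates,
      n_changes = config$n_changes, change_kinds = config$change_kinds,
      delta = config$delta, change_width = config$change_width,
      n_polymorphic = config$n_polymorphic,
      polymorphism_effect = config$polymorphism_effect,
      noise_sd = config$noise_sd, nol_distortion = config$nol_distortion,
      seed = config$seed)
  }
  stopifnot(inherits(experiment, "np_experiment"))
  layout <- experiment$layout
  gts <- names(experiment$truth$genotypes)
  wt <- gts[1]; q <- gts[2]
  sig <- experiment$signals

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mask <- stage("filter_polymorphic",
    filter_polymorphic(sig[[wt]]$reference, sig[[q]]$reference, layout,
                       alpha = config$alpha, min_fraction = config$min_fraction))
  calls <- stage("call_np_changes",
    call_np_changes(sig[[wt]]$nucleosomal, sig[[q]]$nucleosomal,
                    sig[[wt]]$reference, sig[[q]]$reference, layout,
                    mask = mask, alpha = config$alpha,
                    min_span = config$min_span, max_gap = config$max_gap))
  verdicts <- stage("nol_classify",
    nol_classify(calls, sig[[wt]]$nucleosomal, sig[[q]]$nucleosomal, layout,
                 experiment$nol, flank = config$flank,
                 tie_epsilon = config$tie_epsilon))

  keep <- analyzable_windows(mask)
  r_all <- arraywide_correlation(
    average_profile(sig[[wt]]$nucleosomal)[layout$probes$window_id %in% keep],
    average_profile(sig[[q]]$nucleosomal)[layout$probes$window_id %in% keep])

  np_ct <- stage("simulate_ct (MNase-qPCR)",
    simulate_ct(mnase_qpcr_design(genotypes = c(wt, q),
                                  n_samples = config$n_replicates,
                                  protection_ratio = config$qpcr_protection_ratio),
                noise_sd = config$qpcr_noise_sd,
                seed = derive_seed(config$seed, "qpcr_np")))
  np_quant <- stage("relative_np", relative_np(np_ct, target = "Stc1_NP1"))
  expr_ct <- stage("simulate_ct (qRT-PCR)",
    simulate_ct(expression_design(genotypes = c(wt, q),
                                  n_samples = config$n_replicates,
                                  fold = config$qpcr_expression_fold),
                noise_sd = config$qpcr_noise_sd,
                seed = derive_seed(config$seed, "qpcr_expr")))
  expr_quant <- stage("relative_expression",
    relative_expression(expr_ct, target = "Chr106",
                        reference_gene = "UbiConj", calibrator_genotype = wt))

  score <- stage("score_calls",
    score_calls(calls, experiment$truth, overlap_rule = config$overlap_rule,
                mask = mask))

  vt <- table(factor(verdicts$more_correlated,
                     levels = c("mutant", "wild_type", "indeterminate")))
  report <- structure(list(
    config = config,
    seed = config$seed,
    windows = list(total = nrow(layout$windows),
                   analyzable = length(keep),
                   polymorphic = nrow(layout$windows) - length(keep)),
    arraywide_r = r_all,
    calls = list(n = nrow(calls),
                 gain = sum(calls$direction == "gain"),
                 loss = sum(calls$direction == "loss")),
    nol = as.list(vt),
    qpcr = list(
      relative_np_ratio = ratio_query_over_wt(np_quant$groups, wt, q),
      expression_fold = np_quant_fold(expr_quant, q)),
    score = score,
    objects = list(experiment = experiment, mask = mask, calls = calls,
                   verdicts = verdicts, np_quant = np_quant,
                   expr_quant = expr_quant)),
    class = "np_report")

  if (!is.null(config$outdir)) write_report_files(report, config$outdir)
  report
}

ratio_query_over_wt <- function(groups, wt, q) {
  groups$mean[groups$genotype == q] / groups$mean[groups$genotype == wt]
}

np_quant_fold <- function(expr_quant, q) {
  g <- expr_quant$groups
  g$mean[g$genotype == q]
}

write_report_files <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ex <- report$objects$experiment
  layout <- ex$layout
  write_layout(layout, file.path(outdir, "windows.tsv"),
               file.path(outdir, "probes.gff"))
  for (g in names(ex$signals)) {
    write_signal_gff(ex$signals[[g]]$nucleosomal, layout,
                     file.path(outdir, paste0(g, "_nucleosomal.gff")))
    write_signal_gff(ex$signals[[g]]$reference, layout,
                     file.path(outdir, paste0(g, "_reference.gff")))
  }
  write_nol_track(ex$nol, file.path(outdir, "nol.track"))
  write_region_mask(report$objects$mask, file.path(outdir, "mask.json"))
  write_np_calls(report$objects$calls, file.path(outdir, "calls.tsv"))
  utils::write.table(as.data.frame(report$objects$verdicts),
                     file.path(outdir, "nol_verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json(ex$truth, file.path(outdir, "truth.json"))
  summ <- report[c("seed", "windows", "arraywide_r", "calls", "nol", "qpcr")]
  summ$score <- unclass(report$score)
  jsonlite::write_json(summ, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(report)
}

# ground truth as JSON (for provenance alongside written outputs)
truth_json <- function(truth, path) {
  obj <- list(seed = truth$seed, noise_sd = truth$noise_sd,
              genotypes = as.list(truth$genotypes),
              planted_changes = truth$planted_changes,
              planted_polymorphisms = truth$planted_polymorphisms)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(truth)
}

#' @export
print.np_report <- function(x, ...) {
  cat("Differential nucleosome-position pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  windows: %d total, %d analyzable, %d masked polymorphic\n",
              x$windows$total, x$windows$analyzable, x$windows$polymorphic))
  cat(sprintf("  array-wide Pearson r (analyzable probes): %.3f\n", x$arraywide_r))
  cat(sprintf("  NP calls: %d (%d gain, %d loss)\n",
              x$calls$n, x$calls$gain, x$calls$loss))
  cat(sprintf("  NOL verdicts: %d mutant, %d wild_type, %d indeterminate\n",
              x$nol$mutant, x$nol$wild_type, x$nol$indeterminate))
  cat(sprintf("  qPCR: relative NP ratio (query/wt) %.3f; expression fold %.3f\n",
              x$qpcr$relative_np_ratio, x$qpcr$expression_fold))
  print(x$score)
  invisible(x)
}

#' Score NP calls against planted ground truth
#'
#' A planted change interval is recovered when some call overlaps at least
#' `overlap_rule` of the interval with matching direction (`gain`/`loss`);
#' a shift counts as recovered if either its loss part or its gain part is
#' recovered. A call is a true positive if it overlaps any planted interval
#' by at least `overlap_rule` of that interval (direction ignored for
#' precision; direction accuracy is reported separately over
#' truth-matched calls). Planted changes in windows masked polymorphic (if
#' a `mask` is given) are excluded from the denominator, since the pipeline
#' never examines them.
#'
#' @param calls an `np_calls` object
#' @param truth a `synthetic_truth` with planted changes
#' @param overlap_rule minimum recovered fraction of the planted interval
#'   (default 0.5)
#' @param mask optionally, the `region_mask` used for calling
#' @return object of class `np_score`: list with `sensitivity`,
#'   `precision` (`NA` when no calls), `direction_accuracy` (`NA` when no
#'   matched calls), and counts (`n_truth`, `n_calls`, `tp_truth`,
#'   `tp_calls`, `n_matched_direction`)
#' @export
score_calls <- function(calls, truth, overlap_rule = 0.5, mask = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  ch <- truth$planted_changes
  if (!is.null(mask))
    ch <- ch[ch$window_id %in% analyzable_windows(mask), , drop = FALSE]

  overlap_frac <- function(ts, te, cs, ce)
    pmax(0, pmin(te, ce) - pmax(ts, cs) + 1) / (te - ts + 1)

  # per planted interval: recovered by overlap; direction correct among those
  rec <- logical(nrow(ch))
  dir_ok <- logical(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    cc <- calls[calls$window_id == ch$window_id[i], , drop = FALSE]
    if (!nrow(cc)) next
    of <- overlap_frac(ch$start[i], ch$end[i], cc$start, cc$end)
    hit <- of >= overlap_rule
    if (any(hit)) {
      rec[i] <- TRUE
      dir_ok[i] <- any(cc$direction[hit] == ch$kind[i])
    }
  }
  # collapse shift parts: recovered if either part is
  if (nrow(ch)) {
    by_change <- split(seq_len(nrow(ch)), ch$change_id)
    truth_rec <- vapply(by_change, function(ii) any(rec[ii]), logical(1))
    truth_dir <- vapply(by_change, function(ii) any(dir_ok[ii]), logical(1))
    n_truth <- length(by_change)
  } else {
    truth_rec <- truth_dir <- logical(0); n_truth <- 0L
  }

  # per call: does it match any planted interval?
  call_tp <- logical(nrow(calls))
  for (j in seq_len(nrow(calls))) {
    tt <- ch[ch$window_id == calls$window_id[j], , drop = FALSE]
    if (!nrow(tt)) next
    of <- overlap_frac(tt$start, tt$end, calls$start[j], calls$end[j])
    call_tp[j] <- any(of >= overlap_rule)
  }

  structure(list(
    sensitivity = if (n_truth) mean(truth_rec) else NA_real_,
    precision = if (nrow(calls)) mean(call_tp) else NA_real_,
    direction_accuracy = if (any(truth_rec)) mean(truth_dir[truth_rec]) else NA_real_,
    n_truth = n_truth, n_calls = nrow(calls),
    tp_truth = sum(truth_rec), tp_calls = sum(call_tp),
    n_matched_direction = sum(truth_dir)),
    class = "np_score")
}

#' @export
print.np_score <- function(x, ...) {
  cat(sprintf("  truth scoring: sensitivity %s (%d/%d), precision %s (%d/%d), direction accuracy %s\n",
              fmt_or_na(x$sensitivity), x$tp_truth, x$n_truth,
              fmt_or_na(x$precision), x$tp_calls, x$n_calls,
              fmt_or_na(x$direction_accuracy)))
  invisible(x)
}

fmt_or_na <- function(x) if (is.na(x)) "undefined" else sprintf("%.3f", x)
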