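#' Call differential nucleosome-position regions between two genotypes
#'
#' Stage 2 of the pipeline, and the package's core procedure. Within each
#' analyzable window, every probe is tested twice with a pooled-variance
#' Student t-test: wild-type vs query nucleosomal signal, and wild-type vs
#' query reference (genomic DNA) signal. A probe qualifies when the
#' nucleosomal difference is significant (`p <= alpha`) while the reference
#' difference is not (`p > alpha`) — the reference condition is the control
#' against lineage-specific sequence polymorphisms. Maximal runs of
#' consecutive qualifying probes (consecutive = start-to-start distance at
#' most `max_gap`, default the layout step, i.e. no missing tile) whose
#' probe-interval union spans at least `min_span` bp are emitted as calls.
#' Direction is `gain` when the mean query-minus-wild-type averaged-profile
#' difference over the run is positive, `loss` otherwise; an exact zero is
#' tie-broken as `loss` and flagged in the `tie` column.
#'
#' Calls are named `<gene>_NP<k>` with k in 5'-to-3' order within each
#' window, so two qualifying runs separated by a disqualifying probe give
#' `NP1` and `NP2` at one locus.
#'
#' @param wt_nuc,q_nuc nucleosomal-channel [signal_set()]s (wild type, query)
#' @param wt_ref,q_ref reference-channel [signal_set()]s
#' @param layout the shared [probe_layout()]
#' @param mask a `region_mask` from [filter_polymorphic()], or
#'   [all_analyzable_mask()] for same-background comparisons
#' @param alpha per-probe significance level in (0, 1) (default 0.05)
#' @param min_span minimum spanned bp, first probe start to last probe end
#'   (default 140)
#' @param max_gap maximum start-to-start distance between consecutive run
#'   probes (default: the layout step)
#' @param var_equal pooled-variance t by default; `FALSE` for Welch
#' @return An object of class `np_calls`: a data.frame with one row per call
#'   (`window_id`, `gene_id`, `call_name`, `chrom`, `start`, `end`,
#'   `span_bp`, `direction`, `tie`, `n_probes`, `min_nuc_p`, `max_ref_p`,
#'   `mean_delta`), plus attributes `probe_ids` (list of run probe ids),
#'   `probe_stats` (per-probe p-values and qualification flags), and the
#'   calling parameters. Sorted by (window, start).
#' @seealso [arraywide_correlation()], [nol_classify()], [score_calls()]
#' @export
call_np_changes <- function(wt_nuc, q_nuc, wt_ref, q_ref, layout, mask = NULL,
                            alpha = 0.05, min_span = 140L, max_gap = NULL,
                            var_equal = TRUE) {
  stopifnot(inherits(layout, "probe_layout"))
  for (s in list(wt_nuc, q_nuc, wt_ref, q_ref))
    if (!inherits(s, "signal_set")) stop("signal inputs must be signal_set objects")
  check_aligned(layout, wt_nuc, q_nuc, wt_ref, q_ref)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (is.null(mask)) mask <- all_analyzable_mask(layout)
  stopifnot(inherits(mask, "region_mask"))
  if (is.null(max_gap)) max_gap <- layout$step

  nuc <- row_ttest(q_nuc$values, wt_nuc$values, var_equal = var_equal)
  ref <- row_ttest(q_ref$values, wt_ref$values, var_equal = var_equal)
  wt_prof <- average_profile(wt_nuc)
  q_prof <- average_profile(q_nuc)
  delta <- q_prof - wt_prof

  qualifies <- nuc$testable & ref$testable &
    nuc$p <= alpha & ref$p > alpha
  qualifies[is.na(qualifies)] <- FALSE

  p <- layout$probes
  ok_windows <- analyzable_windows(mask)
  calls <- list()
  widx <- split(seq_len(nrow(p)), factor(p$window_id, levels = layout$windows$window_id))
  for (wid in ok_windows) {
    rows <- widx[[wid]]
    if (is.null(rows) || !length(rows)) next
    q <- qualifies[rows]
    if (!any(q)) next
    runs <- find_runs(q, p$start[rows], max_gap)
    if (!length(runs)) next
    wrow <- match(wid, layout$windows$window_id)
    k <- 0L
    for (run in runs) {
      ridx <- rows[run]
      start <- p$start[ridx[1]]
      end <- p$end[ridx[length(ridx)]]
      span <- end - start + 1L
      if (span < min_span) next
      md <- mean(delta[ridx])
      k <- k + 1L
      calls[[length(calls) + 1L]] <- list(
        window_id = wid,
        gene_id = layout$windows$gene_id[wrow],
        k = k,
        chrom = layout$windows$chrom[wrow],
        start = start, end = end, span_bp = span,
        direction = if (md > 0) "gain" else "loss",
        tie = md == 0,
        n_probes = length(ridx),
        min_nuc_p = min(nuc$p[ridx]),
        max_ref_p = max(ref$p[ridx]),
        mean_delta = md,
        probe_ids = p$probe_id[ridx])
    }
  }

  df <- if (length(calls)) {
    data.frame(
      window_id = vapply(calls, `[[`, "", "window_id"),
      gene_id = vapply(calls, `[[`, "", "gene_id"),
      call_name = sprintf("%s_NP%d", vapply(calls, `[[`, "", "gene_id"),
                          vapply(calls, `[[`, 0L, "k")),
      chrom = vapply(calls, `[[`, "", "chrom"),
      start = vapply(calls, `[[`, 0L, "start"),
      end = vapply(calls, `[[`, 0L, "end"),
      span_bp = vapply(calls, `[[`, 0L, "span_bp"),
      direction = vapply(calls, `[[`, "", "direction"),
      tie = vapply(calls, `[[`, FALSE, "tie"),
      n_probes = vapply(calls, `[[`, 0L, "n_probes"),
      min_nuc_p = vapply(calls, `[[`, 0, "min_nuc_p"),
      max_ref_p = vapply(calls, `[[`, 0, "max_ref_p"),
      mean_delta = vapply(calls, `[[`, 0, "mean_delta"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(window_id = character(0), gene_id = character(0),
               call_name = character(0), chrom = character(0),
               start = integer(0), end = integer(0), span_bp = integer(0),
               direction = character(0), tie = logical(0),
               n_probes = integer(0), min_nuc_p = numeric(0),
               max_ref_p = numeric(0), mean_delta = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(df,
            probe_ids = lapply(calls, `[[`, "probe_ids"),
            probe_stats = data.frame(probe_id = p$probe_id,
                                     window_id = p$window_id,
                                     nuc_p = nuc$p, ref_p = ref$p,
                                     qualifies = qualifies,
                                     stringsAsFactors = FALSE),
            alpha = alpha, min_span = min_span, max_gap = max_gap,
            wt_genotype = wt_nuc$genotype, q_genotype = q_nuc$genotype,
            class = c("np_calls", "data.frame"))
}

# maximal runs of TRUE positions with start-to-start distance <= max_gap;
# returns list of integer index vectors (relative to `q`)
find_runs <- function(q, starts, max_gap) {
  idx <- which(q)
  if (!length(idx)) return(list())
  brk <- which(diff(idx) > 1L | diff(starts[idx]) > max_gap)
  grp <- cumsum(c(0L, seq_along(idx)[-1] %in% (brk + 1L)))
  unname(split(idx, grp))
}

#' @export
print.np_calls <- function(x, ...) {
  cat(sprintf("NP calls: %d differential nucleosome-position region(s) [%s vs %s]\n",
              nrow(x), attr(x, "q_genotype"), attr(x, "wt_genotype")))
  cat(sprintf("  alpha = %g, min_span = %d bp, max_gap = %d bp\n",
              attr(x, "alpha"), attr(x, "min_span"), attr(x, "max_gap")))
  if (nrow(x))
    print.data.frame(utils::head(as.data.frame(x)[
      c("call_name", "chrom", "start", "end", "span_bp", "direction", "mean_delta")],
      20), digits = 3)
  invisible(x)
}

#' @export
summary.np_calls <- function(object, ...) {
  out <- list(n_calls = nrow(object),
              n_gain = sum(object$direction == "gain"),
              n_loss = sum(object$direction == "loss"),
              mean_span = if (nrow(object)) mean(object$span_bp) else NA_real_,
              alpha = attr(object, "alpha"),
              min_span = attr(object, "min_span"))
  class(out) <- "summary.np_calls"
  out
}

#' @export
print.summary.np_calls <- function(x, ...) {
  cat(sprintf("%d NP call(s): %d gain, %d loss; mean span %.0f bp (alpha = %g, min span %d bp)\n",
              x$n_calls, x$n_gain, x$n_loss, x$mean_span, x$alpha, x$min_span))
  invisible(x)
}

#' Direction of a nucleosome-position change over a probe run
#'
#' `gain` (of a positioned nucleosome in the query genotype) when the mean
#' query-minus-wild-type profile difference over the run probes is positive,
#' `loss` otherwise. An exact zero is tie-broken as `loss` with `tie = TRUE`.
#'
#' @param probe_ids probe ids of the run (non-empty)
#' @param wt_profile,q_profile named per-probe mean vectors (see
#'   [average_profile()])
#' @return list with `direction` and `tie`
#' @export
classify_direction <- function(probe_ids, wt_profile, q_profile) {
  if (!length(probe_ids)) stop("empty probe run")
  md <- mean(q_profile[probe_ids] - wt_profile[probe_ids])
  list(direction = if (md > 0) "gain" else "loss", tie = md == 0)
}

#' Array-wide Pearson correlation of two probe profiles
#'
#' The global similarity measure between two genotypes' averaged nucleosomal
#' profiles over all analyzable probes. Constant input makes the coefficient
#' undefined and returns `NA` rather than erroring.
#'
#' @param profile_a,profile_b numeric vectors of equal length (per-probe
#'   means); pairs with any `NA` are dropped
#' @return Pearson r, or `NA` if fewer than 2 complete pairs or either
#'   vector is constant
#' @export
arraywide_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  keep <- !(is.na(profile_a) | is.na(profile_b))
  a <- profile_a[keep]; b <- profile_b[keep]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NA_real_)
  stats::cor(a, b)
}

#' Write / read NP calls as tab-delimited text
#'
#' @param calls an `np_calls` object (or plain data.frame of calls)
#' @param path file path
#' @return `write_np_calls` returns `calls` invisibly; `read_np_calls`
#'   returns a data.frame of calls (without probe-level attributes).
#' @export
write_np_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(calls)
}

#' @rdname write_np_calls
#' @export
read_np_calls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(window_id = "character", gene_id = "character",
                                   call_name = "character", chrom = "character",
                                   direction = "character"))
}

#' Plot wild-type and query profiles for one window
#'
#' Reproduces the per-locus profile plot style: the two genotypes' averaged
#' nucleosomal log2-ratio profiles against position relative to the TSS
#' (TSS at 0), with called regions shaded.
#'
#' @param x an `np_calls` object
#' @param layout the [probe_layout()] used for calling
#' @param wt_nuc,q_nuc the nucleosomal [signal_set()]s used for calling
#' @param window_id window to plot (default: the first called window)
#' @param ... passed to [graphics::matplot()]
#' @return invisibly, the plotted data.frame
#' @export
plot.np_calls <- function(x, layout, wt_nuc, q_nuc, window_id = NULL, ...) {
  stopifnot(inherits(layout, "probe_layout"))
  if (is.null(window_id)) {
    if (!nrow(x)) stop("no calls; supply window_id explicitly")
    window_id <- x$window_id[1]
  }
  wrow <- match(window_id, layout$windows$window_id)
  if (is.na(wrow)) stop("unknown window: ", window_id)
  keep <- layout$probes$window_id == window_id
  tss <- layout$windows$tss_offset[wrow]
  pos <- layout$probes$midpoint[keep] - tss
  wt <- average_profile(wt_nuc)[keep]
  q <- average_profile(q_nuc)[keep]
  graphics::matplot(pos, cbind(wt, q), type = "l", lty = 1,
                    col = c("black", "red3"),
                    xlab = "Position relative to TSS (bp)",
                    ylab = "Signal (log2 ratio)",
                    main = layout$windows$gene_id[wrow], ...)
  graphics::abline(v = 0, lty = 3, col = "grey40")
  hits <- x[x$window_id == window_id, , drop = FALSE]
  if (nrow(hits)) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(hits)))
      graphics::rect(hits$start[i] - tss, usr[3], hits$end[i] - tss, usr[4],
                     col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  }
  graphics::legend("topright", bty = "n", lty = 1, col = c("black", "red3"),
                   legend = c(attr(x, "wt_genotype"), attr(x, "q_genotype")))
  invisible(data.frame(pos = pos, wt = wt, query = q))
}
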