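#' Mask windows polymorphic between two genetic backgrounds
#'
#' Stage 1 of the pipeline. Hybridization-based nucleosome-position
#' comparison between haplotypes is confounded wherever the underlying
#' genomic sequence diverges, so windows are first screened using the
#' undigested genomic-DNA (reference) channel: each probe is tested with a
#' two-sample Student t-test between backgrounds, and a window is retained
#' as analyzable only if at least `min_fraction` of its testable probes show
#' no significant difference (`p > alpha`). Untestable probes (fewer than
#' two non-missing replicates in either background) are excluded from both
#' numerator and denominator; a window with zero testable probes is
#' conservatively called polymorphic.
#'
#' @param gdna_a,gdna_b reference-channel [signal_set()]s for the two
#'   backgrounds, on the same layout
#' @param layout the shared [probe_layout()]
#' @param alpha per-probe significance level (default 0.05)
#' @param min_fraction minimum fraction of non-significant probes for a
#'   window to be analyzable (default 0.5, inclusive: exactly half passes)
#' @param var_equal pooled-variance t by default; `FALSE` for Welch
#' @return An object of class `region_mask`: list with `windows`
#'   (data.frame: `window_id`, `verdict` in analyzable/polymorphic,
#'   `frac_ns`, `n_testable`, `n_probes`), `probe_p` (named per-probe gDNA
#'   p-values, `NA` = untestable), `alpha`, `min_fraction`.
#' @export
filter_polymorphic <- function(gdna_a, gdna_b, layout, alpha = 0.05,
                               min_fraction = 0.5, var_equal = TRUE) {
  stopifnot(inherits(gdna_a, "signal_set"), inherits(gdna_b, "signal_set"),
            inherits(layout, "probe_layout"))
  check_aligned(layout, gdna_a, gdna_b)
  if (gdna_a$channel != "reference" || gdna_b$channel != "reference")
    warning("filter_polymorphic expects reference-channel signal sets")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")

  tt <- row_ttest(gdna_a$values, gdna_b$values, var_equal = var_equal)
  win <- layout$probes$window_id
  wids <- layout$windows$window_id
  f <- factor(win, levels = wids)
  n_testable <- as.integer(tapply(tt$testable, f, sum, default = 0L))
  n_ns <- as.integer(tapply(tt$testable & tt$p > alpha, f, sum, default = 0L))
  frac <- ifelse(n_testable > 0, n_ns / n_testable, NA_real_)
  verdict <- ifelse(n_testable > 0 & frac >= min_fraction,
                    "analyzable", "polymorphic")
  probe_p <- stats::setNames(tt$p, layout$probes$probe_id)

  structure(list(
    windows = data.frame(window_id = wids, verdict = verdict, frac_ns = frac,
                         n_testable = n_testable,
                         n_probes = as.integer(table(f)),
                         stringsAsFactors = FALSE),
    probe_p = probe_p, alpha = alpha, min_fraction = min_fraction),
    class = "region_mask")
}

#' An all-analyzable region mask
#'
#' For same-background comparisons where no polymorphism screening applies.
#'
#' @param layout a [probe_layout()]
#' @return a `region_mask` with every window analyzable and per-probe
#'   p-values of 1
#' @export
all_analyzable_mask <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  wids <- layout$windows$window_id
  np <- as.integer(table(factor(layout$probes$window_id, levels = wids)))
  structure(list(
    windows = data.frame(window_id = wids, verdict = "analyzable",
                         frac_ns = 1, n_testable = np, n_probes = np,
                         stringsAsFactors = FALSE),
    probe_p = stats::setNames(rep(1, n_probes(layout)), layout$probes$probe_id),
    alpha = NA_real_, min_fraction = NA_real_),
    class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  n <- nrow(x$windows)
  na_w <- sum(x$windows$verdict == "analyzable")
  cat(sprintf("Region mask: %d of %d windows analyzable (%d polymorphic)\n",
              na_w, n, n - na_w))
  if (!is.na(x$alpha))
    cat(sprintf("  alpha = %g, min_fraction = %g\n", x$alpha, x$min_fraction))
  invisible(x)
}

#' Analyzable window ids of a mask
#' @param mask a `region_mask`
#' @return character vector
#' @export
analyzable_windows <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  mask$windows$window_id[mask$windows$verdict == "analyzable"]
}

#' Serialize / deserialize a region mask as JSON
#'
#' @param mask a `region_mask`
#' @param path file path
#' @return `write_region_mask` returns `mask` invisibly; `read_region_mask`
#'   returns a `region_mask` equal to the one written.
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(inherits(mask, "region_mask"))
  obj <- list(alpha = mask$alpha, min_fraction = mask$min_fraction,
              windows = mask$windows,
              probe_p = as.list(mask$probe_p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = FALSE)
  invisible(mask)
}

#' @rdname write_region_mask
#' @export
read_region_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- as.data.frame(obj$windows, stringsAsFactors = FALSE)
  w$verdict <- as.character(w$verdict)
  w$n_testable <- as.integer(w$n_testable)
  w$n_probes <- as.integer(w$n_probes)
  w$frac_ns <- as.numeric(w$frac_ns)
  pp <- vapply(obj$probe_p, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
               numeric(1))
  structure(list(windows = w, probe_p = pp,
                 alpha = if (is.null(obj$alpha)) NA_real_ else as.numeric(obj$alpha),
                 min_fraction = if (is.null(obj$min_fraction)) NA_real_
                                else as.numeric(obj$min_fraction)),
            class = "region_mask")
}

# shared-layout check used by all multi-signal operations
check_aligned <- function(layout, ...) {
  ids <- layout$probes$probe_id
  for (s in list(...)) {
    if (!identical(rownames(s$values), ids))
      stop("signal set (genotype '", s$genotype, "', channel '", s$channel,
           "') is not aligned to the layout")
  }
  invisible(TRUE)
}
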