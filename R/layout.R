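#' Construct a probe layout
#'
#' A probe layout describes the tiling design of an MNase nucleosome-position
#' microarray: a set of windows, one per gene transcription start site (TSS),
#' each tiled with short probes. The default design mirrors a 3000-bp window
#' per gene tiled end-to-end with 50-bp probes.
#'
#' @param windows data.frame with columns `window_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `tss_offset`, `strand`. Coordinates are 1-based inclusive
#'   (GFF convention); `tss_offset` is the absolute base position of the TSS
#'   and must lie within `[start, end]`.
#' @param probes data.frame with columns `probe_id`, `window_id`, `start`,
#'   `end`. Each probe must lie entirely within its window; probes within a
#'   window must be sorted by start with no duplicated interval.
#' @param probe_length,step design constants in bp, recorded for downstream
#'   continuity rules (`max_gap` defaults to `step` in [call_np_changes()]).
#'
#' @return An object of class `probe_layout`: a list with elements `windows`,
#'   `probes` (with a derived `midpoint` column), `span`, `probe_length`,
#'   `step`, and `probe_index` (named integer vector mapping probe_id to row).
#' @seealso [simulate_layout()] to generate a synthetic design.
#' @export
probe_layout <- function(windows, probes, probe_length = 50L, step = 50L) {
  wcols <- c("window_id", "gene_id", "chrom", "start", "end", "tss_offset", "strand")
  pcols <- c("probe_id", "window_id", "start", "end")
  if (!all(wcols %in% names(windows)))
    stop("windows is missing columns: ", paste(setdiff(wcols, names(windows)), collapse = ", "))
  if (!all(pcols %in% names(probes)))
    stop("probes is missing columns: ", paste(setdiff(pcols, names(probes)), collapse = ", "))
  windows <- as.data.frame(windows)[wcols]
  probes <- as.data.frame(probes)[pcols]
  windows$window_id <- as.character(windows$window_id)
  probes$window_id <- as.character(probes$window_id)
  probes$probe_id <- as.character(probes$probe_id)

  if (anyDuplicated(windows$window_id))
    stop("duplicated window_id in windows")
  if (anyDuplicated(probes$probe_id))
    stop("duplicated probe_id in probes")
  spans <- windows$end - windows$start + 1L
  if (length(unique(spans)) > 1L)
    stop("all windows must share one design span; found spans: ",
         paste(unique(spans), collapse = ", "))
  if (any(windows$tss_offset < windows$start | windows$tss_offset > windows$end))
    stop("tss_offset outside [start, end] for window(s): ",
         paste(windows$window_id[windows$tss_offset < windows$start |
                                 windows$tss_offset > windows$end], collapse = ", "))
  if (any(probes$end < probes$start)) stop("probe end < start")
  if (!all(probes$window_id %in% windows$window_id))
    stop("probes reference unknown window(s): ",
         paste(unique(setdiff(probes$window_id, windows$window_id)), collapse = ", "))

  widx <- match(probes$window_id, windows$window_id)
  if (any(probes$start < windows$start[widx] | probes$end > windows$end[widx]))
    stop("probe(s) extend outside their window")

  # canonical order: window order as given, then probe start
  ord <- order(widx, probes$start, probes$end)
  probes <- probes[ord, , drop = FALSE]
  widx <- widx[ord]
  by_win <- split(seq_len(nrow(probes)), widx)
  for (rows in by_win) {
    if (length(rows) > 1L) {
      s <- probes$start[rows]; e <- probes$end[rows]
      if (any(s[-1] == s[-length(s)] & e[-1] == e[-length(e)]))
        stop("identical probe intervals within a window")
    }
  }
  probes$midpoint <- (probes$start + probes$end) / 2
  rownames(probes) <- NULL
  rownames(windows) <- NULL

  structure(
    list(windows = windows, probes = probes,
         span = spans[1], probe_length = as.integer(probe_length),
         step = as.integer(step),
         probe_index = stats::setNames(seq_len(nrow(probes)), probes$probe_id)),
    class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("Probe layout:", nrow(x$windows), "windows x",
      round(nrow(x$probes) / max(1L, nrow(x$windows)), 1), "probes/window\n")
  cat("  span:", x$span, "bp; probe length:", x$probe_length,
      "bp; step:", x$step, "bp;", nrow(x$probes), "probes total\n")
  invisible(x)
}

#' Number of probes in a layout
#' @param layout a [probe_layout()]
#' @return integer count
#' @export
n_probes <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  nrow(layout$probes)
}

#' Write / read a probe layout as plain-text files
#'
#' The windows table is written as BED-like tab-delimited text (with a header)
#' and the probes as a score-less GFF of `probe` features carrying `probe_id`
#' and `window_id` attributes.
#'
#' @param layout a [probe_layout()]
#' @param windows_path,probes_path file paths
#' @return `write_layout` returns the layout invisibly; `read_layout` returns
#'   a `probe_layout`.
#' @export
write_layout <- function(layout, windows_path, probes_path) {
  stopifnot(inherits(layout, "probe_layout"))
  w <- layout$windows
  utils::write.table(w, windows_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  p <- layout$probes
  wchrom <- layout$windows$chrom[match(p$window_id, layout$windows$window_id)]
  lines <- sprintf("%s\tnucleoshift\tprobe\t%d\t%d\t.\t.\t.\tprobe_id=%s;window_id=%s",
                   wchrom, p$start, p$end, p$probe_id, p$window_id)
  meta <- sprintf("##probe_length=%d step=%d", layout$probe_length, layout$step)
  writeLines(c("##gff-version 3", meta, lines), probes_path)
  invisible(layout)
}

#' @rdname write_layout
#' @export
read_layout <- function(windows_path, probes_path) {
  w <- utils::read.table(windows_path, sep = "\t", header = TRUE,
                         colClasses = c(window_id = "character", gene_id = "character",
                                        chrom = "character", strand = "character"))
  lines <- readLines(probes_path)
  meta <- grep("^##probe_length=", lines, value = TRUE)
  pl <- 50L; st <- 50L
  if (length(meta)) {
    m <- regmatches(meta[1], regexec("probe_length=(\\d+) step=(\\d+)", meta[1]))[[1]]
    pl <- as.integer(m[2]); st <- as.integer(m[3])
  }
  feat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(feat, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed probe GFF line ", bad[1], ": expected 9 tab-delimited fields")
  fm <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  probes <- data.frame(probe_id = attr_get(fm[, 9], "probe_id"),
                       window_id = attr_get(fm[, 9], "window_id"),
                       start = as.integer(fm[, 4]), end = as.integer(fm[, 5]),
                       stringsAsFactors = FALSE)
  probe_layout(w, probes, probe_length = pl, step = st)
}
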