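#' Write probe signals as a GFF-dialect file
#'
#' One feature line per probe per replicate, probes sorted by (window, start).
#' Column 6 carries the signal at full float precision; column 9 carries
#' `probe_id`, `window_id`, `replicate_id`, `genotype` and `channel`
#' attributes. Missing cells are not written.
#'
#' @param signals a [signal_set()]
#' @param layout the [probe_layout()] the signals are aligned to
#' @param path output file
#' @param source value for GFF column 2 (default `"nucleoshift-sim"`)
#' @return the signal set, invisibly
#' @export
write_signal_gff <- function(signals, layout, path, source = "nucleoshift-sim") {
  stopifnot(inherits(signals, "signal_set"), inherits(layout, "probe_layout"))
  p <- layout$probes
  if (!identical(rownames(signals$values), p$probe_id))
    stop("signals are not aligned to the layout")
  chrom <- layout$windows$chrom[match(p$window_id, layout$windows$window_id)]
  lines <- character(0)
  for (j in seq_along(signals$replicate_ids)) {
    v <- signals$values[, j]
    keep <- !is.na(v)
    if (!any(keep)) next
    lines <- c(lines, sprintf(
      "%s\t%s\tprobe_signal\t%d\t%d\t%s\t.\t.\tprobe_id=%s;window_id=%s;replicate_id=%s;genotype=%s;channel=%s",
      chrom[keep], source, p$start[keep], p$end[keep],
      sprintf("%.17g", v[keep]), p$probe_id[keep], p$window_id[keep],
      signals$replicate_ids[j], signals$genotype, signals$channel))
  }
  # interleave replicates per probe, keeping (window, start) probe order
  if (length(lines)) {
    pid <- sub(".*\tprobe_id=([^;]*);.*", "\\1", lines)
    lines <- lines[order(match(pid, p$probe_id))]
  }
  header <- c("##gff-version 3",
              sprintf("##nucleoshift genotype=%s channel=%s units=%s",
                      signals$genotype, signals$channel, signals$units),
              sprintf("##replicates=%s", paste(signals$replicate_ids, collapse = ",")))
  writeLines(c(header, lines), path)
  invisible(signals)
}

#' Read probe signals from a GFF-dialect file
#'
#' Parses the dialect written by [write_signal_gff()] and aligns the scores
#' to `layout`. Cells absent from the file are marked missing (`NA`).
#' Probe ids not present in the layout are reported via a warning and
#' skipped; malformed lines and coordinates outside the probe's declared
#' interval are errors naming the offending line.
#'
#' @param path input file
#' @param layout a [probe_layout()]
#' @return a [signal_set()]
#' @export
read_signal_gff <- function(path, layout) {
  stopifnot(inherits(layout, "probe_layout"))
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#") | !nzchar(lines)
  meta <- lines[is_meta]
  feat_idx <- which(!is_meta)
  genotype <- "unknown"; channel <- "nucleosomal"; units <- NULL
  declared_reps <- NULL
  hm <- grep("^##nucleoshift ", meta, value = TRUE)
  if (length(hm)) {
    g <- regmatches(hm[1], regexec("genotype=(\\S+) channel=(\\S+) units=(\\S+)", hm[1]))[[1]]
    if (length(g) == 4L) { genotype <- g[2]; channel <- g[3]; units <- g[4] }
  }
  rm_line <- grep("^##replicates=", meta, value = TRUE)
  if (length(rm_line)) {
    declared <- sub("^##replicates=", "", rm_line[1])
    declared_reps <- if (nzchar(declared))
      strsplit(declared, ",", fixed = TRUE)[[1]] else character(0)
  }
  if (!length(feat_idx)) {
    reps <- if (is.null(declared_reps)) character(0) else declared_reps
    v <- matrix(NA_real_, n_probes(layout), length(reps),
                dimnames = list(layout$probes$probe_id, reps))
    return(signal_set(layout, v, genotype, channel,
                      replicate_ids = reps, units = units))
  }
  fields <- strsplit(lines[feat_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed GFF line ", feat_idx[bad[1]],
         ": expected 9 tab-delimited fields, found ", lengths(fields)[bad[1]])
  fm <- do.call(rbind, fields)
  score <- suppressWarnings(as.numeric(fm[, 6]))
  if (anyNA(score))
    stop("malformed GFF line ", feat_idx[which(is.na(score))[1]],
         ": non-numeric score")
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
  }
  probe_id <- attr_get(fm[, 9], "probe_id")
  rep_id <- attr_get(fm[, 9], "replicate_id")
  if (anyNA(probe_id) || anyNA(rep_id))
    stop("malformed GFF line ", feat_idx[which(is.na(probe_id) | is.na(rep_id))[1]],
         ": attributes must carry probe_id and replicate_id")

  known <- probe_id %in% layout$probes$probe_id
  if (!all(known)) {
    warning("skipping ", sum(!known), " line(s) with probe ids not in the layout: ",
            paste(utils::head(unique(probe_id[!known]), 5), collapse = ", "))
  }
  ridx <- match(probe_id, layout$probes$probe_id)
  p_start <- layout$probes$start[ridx]
  p_end <- layout$probes$end[ridx]
  start <- as.integer(fm[, 4]); end <- as.integer(fm[, 5])
  mis <- which(known & (start != p_start | end != p_end))
  if (length(mis))
    stop("GFF line ", feat_idx[mis[1]], ": coordinates [", start[mis[1]], ", ",
         end[mis[1]], "] disagree with the layout's probe ", probe_id[mis[1]])

  reps <- if (!is.null(declared_reps)) {
    extra <- setdiff(unique(rep_id), declared_reps)
    c(declared_reps, extra)  # header order wins; undeclared ids appended
  } else unique(rep_id)
  v <- matrix(NA_real_, n_probes(layout), length(reps),
              dimnames = list(layout$probes$probe_id, reps))
  v[cbind(ridx[known], match(rep_id[known], reps))] <- score[known]
  signal_set(layout, v, genotype, channel, replicate_ids = reps, units = units)
}

#' Write / read a nucleosome occupancy likelihood (NOL) track
#'
#' A NOL track holds sequence-intrinsic nucleosome occupancy predictions as
#' two-column (position, score) text per chromosome, with `##chrom=` section
#' headers. Scores are written at full float precision.
#'
#' @param nol an object of class `nol_track` (see [nol_track()])
#' @param path file path
#' @return `write_nol_track` returns `nol` invisibly; `read_nol_track`
#'   returns a `nol_track`.
#' @export
write_nol_track <- function(nol, path) {
  stopifnot(inherits(nol, "nol_track"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##nol-track", con)
  for (ch in unique(nol$chrom)) {
    keep <- nol$chrom == ch
    writeLines(sprintf("##chrom=%s", ch), con)
    writeLines(sprintf("%d\t%.17g", nol$pos[keep], nol$score[keep]), con)
  }
  invisible(nol)
}

#' @rdname write_nol_track
#' @export
read_nol_track <- function(path) {
  lines <- readLines(path)
  chrom <- character(0); pos <- integer(0); score <- numeric(0)
  cur <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, "##chrom=")) { cur <- sub("^##chrom=", "", ln); next }
    if (startsWith(ln, "#") || !nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) stop("malformed NOL track line: ", ln)
    chrom <- c(chrom, cur); pos <- c(pos, as.integer(f[1]))
    score <- c(score, as.numeric(f[2]))
  }
  nol_track(data.frame(chrom = chrom, pos = pos, score = score,
                       stringsAsFactors = FALSE))
}

#' Construct a NOL track
#'
#' @param df data.frame with columns `chrom`, `pos` (1-based base position)
#'   and `score`
#' @return an object of class `nol_track` (a data.frame)
#' @export
nol_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "score") %in% names(df)))
  df <- as.data.frame(df)[c("chrom", "pos", "score")]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("nol_track", "data.frame")
  df
}

#' Sample a NOL track at positions
#'
#' Linear interpolation between track points of the same chromosome; an error
#' names the missing span if any query position falls outside the covered
#' range.
#'
#' @param nol a [nol_track()]
#' @param chrom,pos query chromosome (scalar or vector) and positions
#' @return numeric scores
#' @export
nol_at <- function(nol, chrom, pos) {
  stopifnot(inherits(nol, "nol_track"))
  chrom <- rep_len(as.character(chrom), length(pos))
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    q <- which(chrom == ch)
    keep <- nol$chrom == ch
    if (!any(keep))
      stop("NOL track does not cover chromosome ", ch)
    x <- nol$pos[keep]; y <- nol$score[keep]
    lo <- min(pos[q]); hi <- max(pos[q])
    if (lo < min(x) || hi > max(x))
      stop("NOL track coverage gap on ", ch, ": need [", lo, ", ", hi,
           "], track covers [", min(x), ", ", max(x), "]")
    out[q] <- stats::approx(x, y, xout = pos[q], ties = "ordered")$y
  }
  out
}
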