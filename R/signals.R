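#' Construct a probe signal set
#'
#' A signal set holds one genotype's probe signals for one hybridization
#' channel across replicates. The nucleosomal channel carries the log2 ratio
#' of MNase-digested nucleosomal DNA over undigested DNA; the reference
#' channel carries the undigested genomic-DNA signal on its own scale
#' (recorded in `units`). Each of the study design's pools of biological
#' replicates is one replicate column. Missing cells are `NA`.
#'
#' @param layout a [probe_layout()]
#' @param values numeric matrix, probes x replicates; rownames must equal the
#'   layout's probe ids (any order; rows are realigned to layout order).
#' @param genotype,channel identifiers; `channel` is `"nucleosomal"` or
#'   `"reference"`.
#' @param replicate_ids character vector naming the columns; defaults to
#'   existing colnames or `rep1..repK`.
#' @param units free-text unit annotation (default `"log2_ratio"` for the
#'   nucleosomal channel, `"log2_signal"` otherwise).
#'
#' @return An object of class `signal_set`: list with `genotype`, `channel`,
#'   `replicate_ids`, `units`, and `values` (probes x replicates, rownames =
#'   probe ids in layout order).
#' @export
signal_set <- function(layout, values, genotype, channel = c("nucleosomal", "reference"),
                       replicate_ids = NULL, units = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  channel <- match.arg(channel)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must have probe ids as rownames")
  ids <- layout$probes$probe_id
  if (!setequal(rownames(values), ids))
    stop("row set of values must equal the layout's probe set (",
         nrow(values), " rows vs ", length(ids), " probes)")
  values <- values[ids, , drop = FALSE]
  if (is.null(replicate_ids)) {
    replicate_ids <- colnames(values)
    if (is.null(replicate_ids)) replicate_ids <- paste0("rep", seq_len(ncol(values)))
  }
  stopifnot(length(replicate_ids) == ncol(values))
  colnames(values) <- replicate_ids
  if (is.null(units))
    units <- if (channel == "nucleosomal") "log2_ratio" else "log2_signal"
  structure(list(genotype = as.character(genotype), channel = channel,
                 replicate_ids = as.character(replicate_ids),
                 units = units, values = values),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("Signal set: genotype '%s', channel '%s' (%s)\n",
              x$genotype, x$channel, x$units))
  cat(sprintf("  %d probes x %d replicates; %d missing cells\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Average probe profile across replicates
#'
#' Arithmetic mean over non-missing replicates, per probe, as used for the
#' plotted per-genotype profiles ("three pools of three biological replicates
#' were averaged"). Probes with no non-missing replicate are `NA`.
#'
#' @param signals a [signal_set()]
#' @return named numeric vector, one mean per probe, in layout order
#' @export
average_profile <- function(signals) {
  stopifnot(inherits(signals, "signal_set"))
  rowMeans(signals$values, na.rm = TRUE) |> replace_nan()
}

replace_nan <- function(x) { x[is.nan(x)] <- NA_real_; x }

#' Probes with enough replicates to test
#'
#' Probes need at least `min_reps` non-missing replicates to enter a t-test;
#' probes failing this are untestable and can never seed or extend a called
#' region.
#'
#' @param signals a [signal_set()]
#' @param min_reps minimum non-missing replicates (default 2)
#' @return logical vector in layout order
#' @export
testable_probes <- function(signals, min_reps = 2L) {
  stopifnot(inherits(signals, "signal_set"))
  rowSums(!is.na(signals$values)) >= min_reps
}
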