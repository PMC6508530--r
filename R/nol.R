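#' Classify called regions by correlation with the NOL prediction
#'
#' Stage 3 of the pipeline. Nucleosome occupancy likelihood (NOL) is a
#' sequence-intrinsic prediction of nucleosome occupancy: a mutant profile
#' that correlates with NOL better than the wild type does suggests the
#' wild-type protein normally positions nucleosomes away from their
#' sequence-favored locations. For each call, the NOL track is sampled at
#' the run probes' midpoints (optionally extended by `flank` bp on each
#' side) and a Pearson coefficient is computed separately against each
#' genotype's averaged nucleosomal profile over those probes.
#'
#' The verdict is `mutant` when `r_query > r_wt` strictly, `wild_type` when
#' `r_wt > r_query`, and `indeterminate` when either correlation is
#' undefined (constant input) or the coefficients differ by less than
#' `tie_epsilon`.
#'
#' @param calls an `np_calls` object from [call_np_changes()]
#' @param wt_nuc,q_nuc nucleosomal [signal_set()]s used for the calls
#' @param layout the shared [probe_layout()]
#' @param nol a [nol_track()] covering every sampled probe midpoint (a
#'   coverage gap is an error naming the missing span)
#' @param flank bp added to each side of the call interval before selecting
#'   probes (default 0: the call's probes only)
#' @param tie_epsilon minimum coefficient difference for a decisive verdict
#'   (default 1e-9)
#' @return An object of class `nol_verdicts`: data.frame with `call_name`,
#'   `window_id`, `r_wt`, `r_query`, `more_correlated` in
#'   wild_type/mutant/indeterminate.
#' @export
nol_classify <- function(calls, wt_nuc, q_nuc, layout, nol, flank = 0,
                         tie_epsilon = 1e-9) {
  stopifnot(inherits(calls, "np_calls"), inherits(layout, "probe_layout"),
            inherits(nol, "nol_track"))
  check_aligned(layout, wt_nuc, q_nuc)
  wt_prof <- average_profile(wt_nuc)
  q_prof <- average_profile(q_nuc)
  p <- layout$probes

  n <- nrow(calls)
  r_wt <- r_q <- rep(NA_real_, n)
  verdict <- character(n)
  for (i in seq_len(n)) {
    keep <- p$window_id == calls$window_id[i] &
      p$midpoint >= calls$start[i] - flank &
      p$midpoint <= calls$end[i] + flank
    idx <- which(keep)
    chrom <- calls$chrom[i]
    nol_s <- nol_at(nol, chrom, p$midpoint[idx])
    r_wt[i] <- arraywide_correlation(wt_prof[idx], nol_s)
    r_q[i] <- arraywide_correlation(q_prof[idx], nol_s)
    verdict[i] <- if (is.na(r_wt[i]) || is.na(r_q[i])) "indeterminate"
      else if (abs(r_q[i] - r_wt[i]) < tie_epsilon) "indeterminate"
      else if (r_q[i] > r_wt[i]) "mutant" else "wild_type"
  }
  structure(data.frame(call_name = calls$call_name,
                       window_id = calls$window_id,
                       r_wt = r_wt, r_query = r_q,
                       more_correlated = verdict,
                       stringsAsFactors = FALSE),
            flank = flank, tie_epsilon = tie_epsilon,
            class = c("nol_verdicts", "data.frame"))
}

#' @export
print.nol_verdicts <- function(x, ...) {
  tab <- table(factor(x$more_correlated,
                      levels = c("mutant", "wild_type", "indeterminate")))
  cat(sprintf("NOL verdicts for %d call(s): %d mutant-correlated, %d wild-type-correlated, %d indeterminate\n",
              nrow(x), tab[["mutant"]], tab[["wild_type"]], tab[["indeterminate"]]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 20), digits = 3)
  invisible(x)
}
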