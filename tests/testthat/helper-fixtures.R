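# shared fixtures: tiny layouts, hand-built signal sets, and the
# independent run-enumeration oracle used against call_np_changes

# a minimal hand-built layout: n_windows windows of n_per probes
tiny_layout <- function(n_windows = 1L, n_per = 3L, probe_length = 50L,
                        step = 50L, span = 3000L) {
  i <- seq_len(n_windows)
  windows <- data.frame(
    window_id = sprintf("w%d", i), gene_id = sprintf("g%d", i),
    chrom = "chrT", start = (i - 1L) * (span + 500L) + 1L,
    end = (i - 1L) * (span + 500L) + span,
    tss_offset = (i - 1L) * (span + 500L) + span %/% 2L,
    strand = "+", stringsAsFactors = FALSE)
  probes <- do.call(rbind, lapply(i, function(k) {
    off <- (seq_len(n_per) - 1L) * step
    data.frame(probe_id = sprintf("w%d_p%d", k, seq_len(n_per)),
               window_id = sprintf("w%d", k),
               start = windows$start[k] + off,
               end = windows$start[k] + off + probe_length - 1L,
               stringsAsFactors = FALSE)
  }))
  probe_layout(windows, probes, probe_length = probe_length, step = step)
}

# signal set from a probe x replicate matrix (rows in layout order)
make_signals <- function(layout, values, genotype = "gt",
                         channel = "nucleosomal") {
  values <- as.matrix(values)
  rownames(values) <- layout$probes$probe_id
  signal_set(layout, values, genotype, channel)
}

# constant-profile signal set with optional per-replicate noise
flat_signals <- function(layout, level = 0, n_rep = 3L, genotype = "gt",
                         channel = "reference", noise_sd = 0) {
  v <- matrix(level, n_probes(layout), n_rep)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  make_signals(layout, v, genotype, channel)
}

# --- independent oracle for the NP caller --------------------------------
# Enumerates every contiguous probe run in each window, evaluates the dual
# t-test condition and the span rule per run with stats::t.test, and keeps
# maximal qualifying runs. Deliberately brute force and structured nothing
# like find_runs()/call_np_changes().
oracle_np_calls <- function(wt_nuc, q_nuc, wt_ref, q_ref, layout,
                            alpha = 0.05, min_span = 140L, max_gap = NULL) {
  if (is.null(max_gap)) max_gap <- layout$step
  safe_p <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  out <- list()
  for (wid in layout$windows$window_id) {
    rows <- which(layout$probes$window_id == wid)
    n <- length(rows)
    qual <- logical(n)
    for (k in seq_len(n)) {
      pn <- safe_p(q_nuc$values[rows[k], ], wt_nuc$values[rows[k], ])
      pr <- safe_p(q_ref$values[rows[k], ], wt_ref$values[rows[k], ])
      qual[k] <- !is.na(pn) && !is.na(pr) && pn <= alpha && pr > alpha
    }
    starts <- layout$probes$start[rows]
    ends <- layout$probes$end[rows]
    contiguous <- function(i, j) {
      if (i == j) return(TRUE)
      all(qual[i:j]) && all(diff(starts[i:j]) <= max_gap)
    }
    for (i in seq_len(n)) for (j in i:n) {
      if (!all(qual[i:j])) next
      if (!contiguous(i, j)) next
      # maximal: no qualifying contiguous extension on either side
      left_ext <- i > 1 && qual[i - 1] && starts[i] - starts[i - 1] <= max_gap
      right_ext <- j < n && qual[j + 1] && starts[j + 1] - starts[j] <= max_gap
      if (left_ext || right_ext) next
      if (ends[j] - starts[i] + 1 < min_span) next
      out[[length(out) + 1L]] <- data.frame(
        window_id = wid, start = starts[i], end = ends[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(window_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$window_id, res$start), , drop = FALSE]
}

# random small instance for oracle comparison: planted per-probe shifts in
# both channels plus occasional missing cells
random_instance <- function(layout, n_rep = 3L) {
  np <- n_probes(layout)
  shift_nuc <- sample(c(0, 3), np, replace = TRUE, prob = c(0.5, 0.5))
  shift_ref <- sample(c(0, 3), np, replace = TRUE, prob = c(0.8, 0.2))
  wt_n <- matrix(rnorm(np * n_rep), np)
  q_n <- matrix(rnorm(np * n_rep), np) + shift_nuc
  wt_r <- matrix(rnorm(np * n_rep), np)
  q_r <- matrix(rnorm(np * n_rep), np) + shift_ref
  # knock out a whole replicate row for ~5% of probes (untestable)
  ko <- runif(np) < 0.05
  q_n[ko, -1] <- NA
  list(wt_nuc = make_signals(layout, wt_n, "wt", "nucleosomal"),
       q_nuc = make_signals(layout, q_n, "mut", "nucleosomal"),
       wt_ref = make_signals(layout, wt_r, "wt", "reference"),
       q_ref = make_signals(layout, q_r, "mut", "reference"))
}
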