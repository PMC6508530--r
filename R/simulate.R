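#' Simulate a tiling-array probe layout
#'
#' Windows (one per synthetic gene TSS) are placed on synthetic chromosomes,
#' 50 windows per chromosome, and tiled end-to-end with probes. The default
#' design is the study scale: a 3000-bp window per gene tiled with 50-bp
#' probes at 50-bp steps (60 probes per window); with 400 windows that is
#' 24000 probes. The TSS sits at the window center and gene strands are
#' drawn at random (deterministically under `seed`).
#'
#' @param n_windows number of TSS windows
#' @param span window span in bp (default 3000)
#' @param probe_length,step probe geometry in bp (defaults 50/50)
#' @param seed integer RNG seed; the same seed always yields the same layout
#' @return a [probe_layout()]
#' @export
simulate_layout <- function(n_windows, span = 3000L, probe_length = 50L,
                            step = 50L, seed = 1L) {
  if (n_windows < 1 || span < 1 || probe_length < 1 || step < 1)
    stop("n_windows, span, probe_length and step must be positive")
  if (span < probe_length) stop("span must be at least probe_length")
  with_seed(derive_seed(seed, "layout"), {
    per_chrom <- 50L
    i <- seq_len(n_windows)
    chrom <- sprintf("chrS%02d", 1L + (i - 1L) %/% per_chrom)
    slot <- (i - 1L) %% per_chrom
    start <- slot * (span + 1000L) + 1L
    end <- start + span - 1L
    windows <- data.frame(
      window_id = sprintf("win%04d", i),
      gene_id = sprintf("GeneS%04d", i),
      chrom = chrom, start = start, end = end,
      tss_offset = start + span %/% 2L,
      strand = sample(c("+", "-"), n_windows, replace = TRUE),
      stringsAsFactors = FALSE)
    n_per <- ((span - probe_length) %/% step) + 1L
    off <- rep(seq_len(n_per) - 1L, times = n_windows) * step
    wrep <- rep(i, each = n_per)
    probes <- data.frame(
      probe_id = sprintf("win%04d_p%03d", wrep, rep(seq_len(n_per), times = n_windows)),
      window_id = sprintf("win%04d", wrep),
      start = windows$start[wrep] + off,
      end = windows$start[wrep] + off + probe_length - 1L,
      stringsAsFactors = FALSE)
    probe_layout(windows, probes, probe_length = probe_length, step = step)
  })
}

#' Simulate experiment ground truth
#'
#' Builds the hidden state of a synthetic nucleosome-positioning experiment:
#' per-genotype positioned-nucleosome configurations (Gaussian peaks with a
#' nucleosome-free region at the TSS), planted nucleosome-position changes
#' (gain, loss, or shift — a shift is recorded as a loss interval plus an
#' adjacent gain interval) in the non-wild-type genotype, and planted
#' polymorphic windows for genotypes on a different haplotype than the
#' first (reference) genotype.
#'
#' A planted loss multiplies the affected nucleosome's height by
#' `2^-delta`. A planted gain adds a positioned nucleosome of height
#' `height_ref * (2^delta - 1)` (a full-height nucleosome appears at
#' `delta = 1`) at the interval center; because a new nucleosome needs an
#' open region to occupy, one base nucleosome is removed from every
#' genotype's configuration at that position first (likewise for the gain
#' part of a shift). Both genotypes therefore remain identical outside the
#' planted intervals.
#'
#' @param layout a [probe_layout()]
#' @param genotypes named character vector: names are genotype labels (first
#'   = wild type / reference), values are haplotype labels
#' @param n_changes number of windows given one planted change each
#' @param change_kinds kinds to cycle through (`gain`, `loss`, `shift`)
#' @param delta planted effect size in log2 units
#' @param change_width planted interval width in bp (default 200)
#' @param n_polymorphic number of windows given a planted haplotype
#'   polymorphism (affecting both channels of non-reference haplotypes)
#' @param polymorphism_effect gDNA divergence effect size in log2 units
#' @param nucleosome_sd Gaussian nucleosome fuzziness in bp (default 30,
#'   footprint ~150 bp)
#' @param nucleosome_spacing mean center-to-center distance in bp
#' @param height_range positioned-nucleosome occupancy height range
#' @param noise_sd per-replicate noise SD, log2 units (both channels)
#' @param seed integer; fully determines all generator output
#' @return object of class `synthetic_truth`: list with `nucleosomes`
#'   (per-genotype data.frame: `window_id`, `center`, `sd`, `height`),
#'   `planted_changes` (`change_id`, `window_id`, `start`, `end`, `kind`
#'   in gain/loss, `parent_kind` in gain/loss/shift, `delta`),
#'   `planted_polymorphisms` (`window_id`, `start`, `end`, `effect`),
#'   `genotypes`, `noise_sd`, model constants, `seed`.
#' @export
simulate_truth <- function(layout, genotypes = c(wild_type = "ref", mutant = "alt"),
                           n_changes = 50L, change_kinds = c("gain", "loss"),
                           delta = 1.0, change_width = 200L,
                           n_polymorphic = 40L, polymorphism_effect = 2.0,
                           nucleosome_sd = 30, nucleosome_spacing = 200L,
                           height_range = c(0.7, 1.0), noise_sd = 0.2,
                           seed = 1L) {
  stopifnot(inherits(layout, "probe_layout"))
  if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
    stop("genotypes must be a named vector (name = genotype, value = haplotype)")
  stopifnot(all(change_kinds %in% c("gain", "loss", "shift")))
  w <- layout$windows
  n_win <- nrow(w)
  if (n_polymorphic + n_changes > n_win)
    stop("n_polymorphic + n_changes exceeds the number of windows")

  with_seed(derive_seed(seed, "truth"), {
    # base nucleosome configuration, shared by all genotypes
    base <- vector("list", n_win)
    for (i in seq_len(n_win)) {
      centers <- seq(w$start[i] + nucleosome_spacing %/% 2L,
                     w$end[i] - nucleosome_spacing %/% 2L,
                     by = nucleosome_spacing)
      centers <- centers + round(stats::runif(length(centers), -20, 20))
      centers <- centers[abs(centers - w$tss_offset[i]) > 80]  # TSS-proximal NFR
      base[[i]] <- data.frame(window_id = w$window_id[i], center = centers,
                              sd = nucleosome_sd,
                              height = stats::runif(length(centers),
                                                    height_range[1], height_range[2]),
                              stringsAsFactors = FALSE)
    }

    pick <- sample(n_win, n_polymorphic + n_changes)
    poly_w <- sort(pick[seq_len(n_polymorphic)])
    change_w <- sort(pick[n_polymorphic + seq_len(n_changes)])

    # polymorphic intervals cover the central 80% of the window, so a clear
    # majority of probes diverges and the filter flags the window
    planted_polymorphisms <- if (n_polymorphic > 0) {
      data.frame(window_id = w$window_id[poly_w],
                 start = w$start[poly_w] + as.integer(0.1 * layout$span),
                 end = w$end[poly_w] - as.integer(0.1 * layout$span),
                 effect = polymorphism_effect, stringsAsFactors = FALSE)
    } else {
      data.frame(window_id = character(0), start = integer(0),
                 end = integer(0), effect = numeric(0))
    }

    href <- mean(height_range)
    kinds <- rep_len(change_kinds, n_changes)
    changes <- list()
    for (j in seq_along(change_w)) {
      i <- change_w[j]
      nuc <- base[[i]]
      kind <- kinds[j]
      half <- change_width %/% 2L
      margin <- w$start[i] + half + 10L
      if (kind == "loss") {
        ok <- which(nuc$center >= margin & nuc$center <= w$end[i] - half - 10L)
        if (!length(ok)) next
        c0 <- nuc$center[ok[ceiling(length(ok) / 2)]]
        changes[[length(changes) + 1L]] <- data.frame(
          change_id = sprintf("chg%03d", j), window_id = w$window_id[i],
          start = c0 - half, end = c0 + half - 1L, kind = "loss",
          parent_kind = "loss", delta = delta, stringsAsFactors = FALSE)
      } else if (kind == "gain") {
        # a gained nucleosome needs an open region: drop one base nucleosome
        # from every genotype and plant the gain at its former center
        ok <- which(nuc$center >= margin & nuc$center <= w$end[i] - half - 10L)
        if (!length(ok)) next
        sel <- ok[ceiling(length(ok) / 2)]
        c0 <- nuc$center[sel]
        base[[i]] <- nuc[-sel, , drop = FALSE]
        changes[[length(changes) + 1L]] <- data.frame(
          change_id = sprintf("chg%03d", j), window_id = w$window_id[i],
          start = c0 - half, end = c0 + half - 1L, kind = "gain",
          parent_kind = "gain", delta = delta, stringsAsFactors = FALSE)
      } else { # shift: drop the right neighbor so the slid nucleosome has room
        ok <- which(nuc$center >= margin &
                    nuc$center <= w$end[i] - 3L * half - 10L)
        ok <- ok[ok < nrow(nuc)]
        if (!length(ok)) next
        sel <- ok[ceiling(length(ok) / 2)]
        c0 <- nuc$center[sel]
        base[[i]] <- nuc[-(sel + 1L), , drop = FALSE]
        changes[[length(changes) + 1L]] <- data.frame(
          change_id = sprintf("chg%03d", j), window_id = rep(w$window_id[i], 2),
          start = c(c0 - half, c0 + half),
          end = c(c0 + half - 1L, c0 + 3L * half - 1L),
          kind = c("loss", "gain"), parent_kind = "shift",
          delta = delta, stringsAsFactors = FALSE)
      }
    }
    planted_changes <- if (length(changes)) do.call(rbind, changes) else
      data.frame(change_id = character(0), window_id = character(0),
                 start = integer(0), end = integer(0), kind = character(0),
                 parent_kind = character(0), delta = numeric(0))
    rownames(planted_changes) <- NULL

    base_df <- do.call(rbind, base)
    rownames(base_df) <- NULL
    nucleosomes <- stats::setNames(vector("list", length(genotypes)), names(genotypes))
    for (g in names(genotypes)) {
      cfg <- base_df
      if (g != names(genotypes)[1] && nrow(planted_changes)) {
        cfg <- apply_changes(cfg, planted_changes, href)
      }
      nucleosomes[[g]] <- cfg
    }

    structure(list(nucleosomes = nucleosomes,
                   planted_changes = planted_changes,
                   planted_polymorphisms = planted_polymorphisms,
                   genotypes = genotypes,
                   noise_sd = noise_sd, nucleosome_sd = nucleosome_sd,
                   height_ref = href, seed = as.integer(seed)),
              class = "synthetic_truth")
  })
}

# bake planted gains/losses into a nucleosome configuration
apply_changes <- function(cfg, changes, href) {
  for (r in seq_len(nrow(changes))) {
    ch <- changes[r, ]
    if (ch$kind == "loss") {
      hit <- cfg$window_id == ch$window_id &
        cfg$center >= ch$start & cfg$center <= ch$end
      cfg$height[hit] <- cfg$height[hit] * 2^(-ch$delta)
    } else {
      cfg <- rbind(cfg, data.frame(
        window_id = ch$window_id,
        center = (ch$start + ch$end) / 2,
        sd = cfg$sd[1], height = href * (2^ch$delta - 1),
        stringsAsFactors = FALSE))
    }
  }
  cfg[order(cfg$window_id, cfg$center), , drop = FALSE]
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", length(x$genotypes), "genotype(s) [",
      paste(names(x$genotypes), collapse = ", "), "]\n")
  cat(sprintf("  %d planted change interval(s), %d polymorphic window(s), noise_sd = %g, seed = %d\n",
              nrow(x$planted_changes), nrow(x$planted_polymorphisms),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Per-base nucleosome occupancy of a genotype
#'
#' Occupancy is the clamped sum of Gaussian nucleosome peaks:
#' `occ(x) = min(1, sum_j h_j * exp(-(x - c_j)^2 / (2 sd_j^2)))`.
#' Planted gains and losses are already baked into each genotype's
#' nucleosome configuration by [simulate_truth()].
#'
#' @param truth a `synthetic_truth`
#' @param layout the [probe_layout()] the truth was built on
#' @param genotype genotype label
#' @param window_id window to evaluate
#' @param pos base positions (default: every base of the window)
#' @return numeric occupancy in `[0, 1]` at `pos`
#' @export
simulate_occupancy <- function(truth, layout, genotype, window_id, pos = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!genotype %in% names(truth$genotypes))
    stop("unknown genotype: ", genotype)
  wrow <- match(window_id, layout$windows$window_id)
  if (is.na(wrow)) stop("unknown window: ", window_id)
  if (is.null(pos))
    pos <- layout$windows$start[wrow]:layout$windows$end[wrow]
  nuc <- truth$nucleosomes[[genotype]]
  nuc <- nuc[nuc$window_id == window_id, , drop = FALSE]
  occ <- numeric(length(pos))
  for (j in seq_len(nrow(nuc)))
    occ <- occ + nuc$height[j] * exp(-(pos - nuc$center[j])^2 / (2 * nuc$sd[j]^2))
  pmin(occ, 1)
}

#' Simulate two-channel probe signals for one genotype
#'
#' The nucleosomal-channel value of a probe is
#' `log2(mean occupancy over the probe interval * dynamic_range +
#' occupancy_floor)` plus independent per-replicate Gaussian noise; the
#' reference (undigested genomic DNA) channel is a flat baseline plus
#' noise. Inside planted polymorphic intervals, genotypes on a non-reference
#' haplotype are shifted by the divergence effect size in both channels.
#' Output is fully determined by the truth's seed, the genotype and the
#' channel, regardless of call order.
#'
#' @param layout a [probe_layout()]
#' @param truth a `synthetic_truth` built on `layout`
#' @param genotype genotype label (must exist in the truth)
#' @param n_replicates replicate columns to draw (default 3: three pools of
#'   three biological replicates)
#' @param occupancy_floor background signal at zero occupancy, linear scale
#'   (default 0.02: linker-level MNase background)
#' @param dynamic_range linear scale factor from occupancy to signal
#' @param ref_baseline reference-channel baseline, log2 units
#' @return list with elements `nucleosomal` and `reference`, each a
#'   [signal_set()]
#' @export
simulate_signals <- function(layout, truth, genotype, n_replicates = 3L,
                             occupancy_floor = 0.02, dynamic_range = 1,
                             ref_baseline = 0) {
  stopifnot(inherits(layout, "probe_layout"), inherits(truth, "synthetic_truth"))
  if (!genotype %in% names(truth$genotypes))
    stop("unknown genotype: ", genotype)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  p <- layout$probes
  w <- layout$windows

  # noiseless per-probe nucleosomal mean via per-window cumulative sums
  mean_occ <- numeric(nrow(p))
  for (i in seq_len(nrow(w))) {
    rows <- which(p$window_id == w$window_id[i])
    if (!length(rows)) next
    occ <- simulate_occupancy(truth, layout, genotype, w$window_id[i])
    cs <- cumsum(c(0, occ))
    s <- p$start[rows] - w$start[i] + 1L
    e <- p$end[rows] - w$start[i] + 1L
    mean_occ[rows] <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
  }
  nuc_base <- log2(mean_occ * dynamic_range + occupancy_floor)
  ref_base <- rep(ref_baseline, nrow(p))

  # haplotype divergence perturbs both channels
  ref_hap <- truth$genotypes[[1]]
  if (truth$genotypes[[genotype]] != ref_hap && nrow(truth$planted_polymorphisms)) {
    pp <- truth$planted_polymorphisms
    for (r in seq_len(nrow(pp))) {
      hit <- p$window_id == pp$window_id[r] &
        p$midpoint >= pp$start[r] & p$midpoint <= pp$end[r]
      nuc_base[hit] <- nuc_base[hit] + pp$effect[r]
      ref_base[hit] <- ref_base[hit] + pp$effect[r]
    }
  }

  rep_ids <- paste0("pool", seq_len(n_replicates))
  out <- list()
  for (channel in c("nucleosomal", "reference")) {
    base <- if (channel == "nucleosomal") nuc_base else ref_base
    vals <- with_seed(derive_seed(truth$seed, "signals", genotype, channel), {
      base + matrix(stats::rnorm(nrow(p) * n_replicates, 0, truth$noise_sd),
                    nrow(p), n_replicates)
    })
    rownames(vals) <- p$probe_id
    out[[channel]] <- signal_set(layout, vals, genotype, channel,
                                 replicate_ids = rep_ids)
  }
  out
}

#' Simulate a nucleosome occupancy likelihood (NOL) track
#'
#' The NOL emulates a sequence-intrinsic occupancy prediction: it equals the
#' occupancy profile of the designated sequence-favored genotype
#' configuration (the configuration mutants are expected to relax toward),
#' optionally distorted by smooth correlated noise. `distortion = 0`
#' reproduces that configuration's occupancy exactly.
#'
#' @param layout a [probe_layout()]
#' @param truth a `synthetic_truth`
#' @param reference_genotype genotype whose configuration is sequence-favored
#' @param distortion fraction in `[0, 1]` blending in a smooth random field
#' @param track_step sampling step of the track in bp (default 10)
#' @return a [nol_track()] covering every window
#' @export
simulate_nol <- function(layout, truth, reference_genotype, distortion = 0,
                         track_step = 10L) {
  stopifnot(inherits(layout, "probe_layout"), inherits(truth, "synthetic_truth"))
  if (distortion < 0 || distortion > 1) stop("distortion must lie in [0, 1]")
  w <- layout$windows
  pieces <- vector("list", nrow(w))
  with_seed(derive_seed(truth$seed, "nol"), {
    for (i in seq_len(nrow(w))) {
      pos <- seq(w$start[i], w$end[i], by = track_step)
      if (pos[length(pos)] < w$end[i]) pos <- c(pos, w$end[i])
      occ <- simulate_occupancy(truth, layout, reference_genotype,
                                w$window_id[i], pos = pos)
      if (distortion > 0) {
        knots <- seq(w$start[i], w$end[i], length.out = 21)
        field <- stats::approx(knots, stats::rnorm(21), xout = pos)$y
        occ <- (1 - distortion) * occ + distortion * field
      }
      pieces[[i]] <- data.frame(chrom = w$chrom[i], pos = pos, score = occ,
                                stringsAsFactors = FALSE)
    }
  })
  nol_track(do.call(rbind, pieces))
}

#' Simulate a qPCR Ct table from true template quantities
#'
#' Each design row gives the true relative template quantity of one
#' (target, sample, assay) reaction; `Ct = intercept - log2(quantity)` plus
#' per-well Gaussian noise, with `n_tech` technical replicates per reaction
#' (default 2). Perfect per-cycle doubling: halving the quantity raises Ct
#' by exactly one cycle at zero noise.
#'
#' @param design data.frame with columns `target`, `sample_id`, `genotype`,
#'   `assay`, `quantity` (> 0)
#' @param noise_sd per-well Ct noise SD in cycles
#' @param seed integer RNG seed
#' @param n_tech technical replicates per reaction
#' @param intercept Ct of a unit-quantity template (default 20 cycles)
#' @return a [ct_table()]
#' @export
simulate_ct <- function(design, noise_sd = 0.1, seed = 1L, n_tech = 2L,
                        intercept = 20) {
  cols <- c("target", "sample_id", "genotype", "assay", "quantity")
  if (!all(cols %in% names(design)))
    stop("design is missing columns: ", paste(setdiff(cols, names(design)), collapse = ", "))
  if (any(!is.finite(design$quantity) | design$quantity <= 0))
    stop("quantities must be positive")
  n <- nrow(design)
  idx <- rep(seq_len(n), each = n_tech)
  ct <- with_seed(derive_seed(seed, "ct"), {
    intercept - log2(design$quantity[idx]) +
      stats::rnorm(n * n_tech, 0, noise_sd)
  })
  ct_table(data.frame(target = design$target[idx],
                      sample_id = design$sample_id[idx],
                      genotype = design$genotype[idx],
                      assay = design$assay[idx],
                      tech_rep = rep(seq_len(n_tech), times = n),
                      ct = ct, stringsAsFactors = FALSE))
}

#' Design tables for simulated qPCR experiments
#'
#' `mnase_qpcr_design` lays out an MNase-protection assay: target and
#' control locus, each with `mnase` and `gdna` templates per sample, where
#' the query group's target MNase quantity is scaled by `protection_ratio`
#' (0.5 = half the protection of wild type). `expression_design` lays out a
#' qRT-PCR assay where the query group's target cDNA quantity is scaled by
#' `fold`.
#'
#' @param genotypes length-2 character vector, wild type first
#' @param n_samples biological samples per group
#' @param protection_ratio,fold planted query-vs-wild-type ratio
#' @param target,control_locus,reference_gene locus/gene names
#' @return a design data.frame for [simulate_ct()]
#' @export
mnase_qpcr_design <- function(genotypes = c("wild_type", "mutant"), n_samples = 3L,
                              protection_ratio = 0.5, target = "Stc1_NP1",
                              control_locus = "Mwp1") {
  rows <- list()
  for (g in genotypes) for (s in seq_len(n_samples)) {
    sid <- paste0(g, "_s", s)
    scale <- if (g == genotypes[1]) 1 else protection_ratio
    rows[[length(rows) + 1L]] <- data.frame(
      target = c(target, target, control_locus, control_locus),
      sample_id = sid, genotype = g,
      assay = c("mnase", "gdna", "mnase", "gdna"),
      quantity = c(scale, 1, 1, 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @rdname mnase_qpcr_design
#' @export
expression_design <- function(genotypes = c("wild_type", "mutant"), n_samples = 3L,
                              fold = 0.5, target = "Chr106",
                              reference_gene = "UbiConj") {
  rows <- list()
  for (g in genotypes) for (s in seq_len(n_samples)) {
    sid <- paste0(g, "_s", s)
    scale <- if (g == genotypes[1]) 1 else fold
    rows[[length(rows) + 1L]] <- data.frame(
      target = c(target, reference_gene),
      sample_id = sid, genotype = g, assay = "cdna",
      quantity = c(scale, 1), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a complete synthetic experiment
#'
#' One call builds everything the pipeline consumes, at the study's scale
#' by default: a 400-window / 3000-bp / 50-bp-probe layout, ground truth
#' with 50 planted nucleosome-position changes (delta = 1 log2) and 40
#' polymorphic windows, two-channel signal sets with 3 replicate pools per
#' genotype at noise SD 0.2, and a NOL track equal to the query genotype's
#' configuration (mutants relax toward sequence-favored positions).
#'
#' @param n_windows,span,probe_length,step layout parameters
#' @param genotypes named vector (genotype = haplotype), wild type first
#' @param n_replicates replicate pools per genotype
#' @param n_changes,change_kinds,delta,change_width planted-change parameters
#' @param n_polymorphic,polymorphism_effect planted-polymorphism parameters
#' @param noise_sd replicate noise SD in log2 units
#' @param nol_genotype genotype whose configuration the NOL reproduces
#'   (default: the second, query genotype)
#' @param nol_distortion smooth-noise blend for the NOL track
#' @param seed integer; determines every random draw
#' @param ... further arguments to [simulate_truth()] or [simulate_signals()]
#'   (`nucleosome_sd`, `nucleosome_spacing`, `height_range`,
#'   `occupancy_floor`, `dynamic_range`, `ref_baseline`)
#' @return object of class `np_experiment`: list with `layout`, `truth`,
#'   `signals` (per genotype: `nucleosomal` and `reference` signal sets),
#'   `nol`, and `seed`
#' @export
simulate_experiment <- function(n_windows = 400L, span = 3000L,
                                probe_length = 50L, step = 50L,
                                genotypes = c(wild_type = "ref", mutant = "alt"),
                                n_replicates = 3L,
                                n_changes = 50L, change_kinds = c("gain", "loss"),
                                delta = 1.0, change_width = 200L,
                                n_polymorphic = 40L, polymorphism_effect = 2.0,
                                noise_sd = 0.2,
                                nol_genotype = names(genotypes)[2],
                                nol_distortion = 0, seed = 1L, ...) {
  extra <- list(...)
  truth_args <- extra[names(extra) %in%
    c("nucleosome_sd", "nucleosome_spacing", "height_range")]
  sig_args <- extra[names(extra) %in%
    c("occupancy_floor", "dynamic_range", "ref_baseline")]
  layout <- simulate_layout(n_windows, span, probe_length, step, seed = seed)
  truth <- do.call(simulate_truth, c(list(
    layout = layout, genotypes = genotypes, n_changes = n_changes,
    change_kinds = change_kinds, delta = delta, change_width = change_width,
    n_polymorphic = n_polymorphic, polymorphism_effect = polymorphism_effect,
    noise_sd = noise_sd, seed = seed), truth_args))
  signals <- lapply(stats::setNames(names(genotypes), names(genotypes)),
                    function(g) do.call(simulate_signals, c(list(
                      layout = layout, truth = truth, genotype = g,
                      n_replicates = n_replicates), sig_args)))
  nol <- simulate_nol(layout, truth, reference_genotype = nol_genotype,
                      distortion = nol_distortion)
  structure(list(layout = layout, truth = truth, signals = signals,
                 nol = nol, seed = as.integer(seed)),
            class = "np_experiment")
}

#' @export
print.np_experiment <- function(x, ...) {
  cat("Synthetic nucleosome-positioning experiment (seed", x$seed, ")\n")
  print(x$layout)
  print(x$truth)
  invisible(x)
}

# --- deterministic seeding helpers ---------------------------------------

# derive a stream-specific 31-bit seed from a base seed and labels
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 131 + ch) %% 1009001
  as.integer((as.numeric(seed) * 2654435 + h * 97 + 12345) %% 2147483647)
}

# evaluate expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
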