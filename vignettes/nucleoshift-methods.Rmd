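---
title: "Methods: differential nucleosome-position calling and its synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential nucleosome-position calling and its synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoshift)
```

## The measurement and its statistical model

An MNase-protection tiling array measures, per probe, the log2 ratio of
MNase-digested mono-/di-nucleosomal DNA to undigested genomic DNA over
3000-bp windows centered on gene transcription start sites (TSSs). Peaks in
this profile mark positioned nucleosomes; valleys mark linker or
nucleosome-free DNA. Each genotype contributes replicate pools (three by
default — each pool of biological replicates is one replicate column; any
pooling happens upstream), in two channels:

* **nucleosomal**: the log2 MNase/undigested ratio, the quantity of
  interest;
* **reference**: the undigested genomic DNA signal, which carries no
  chromatin information and therefore serves two control purposes —
  exposing sequence divergence between genetic backgrounds, and guarding
  individual calls against residual polymorphism.

All probe-level comparisons use the classical pooled-variance two-sample
Student *t* (`probe_ttest`), two-sided, with `df = n_a + n_b - 2`. Degenerate
inputs follow fixed conventions instead of erroring, because real arrays
contain saturated probes: both groups constant and equal gives *p* = 1,
constant and unequal gives *p* = 0, and fewer than two non-missing values in
either group makes a probe *untestable* — it can never seed or extend a
called region, and it is excluded from both numerator and denominator of the
polymorphism filter's retention fraction. A Welch option (`var_equal =
FALSE`) exists but the pooled test is the default, matching how such probe
tests are conventionally run. No multiple-testing correction is applied at
the probe level: the run-length requirement below is the effective guard
against isolated false positives, and corrections would change the
operating characteristics the calibration below measures.

## Stage 1 — polymorphism masking

For two genetic backgrounds, every probe is tested on the reference channel.
A window is **analyzable** when at least `min_fraction` (default 0.5,
inclusive — exactly half passes) of its testable probes show *p* > α
(default 0.05); otherwise it is **polymorphic** and excluded from all later
stages. A window with no testable probe is conservatively polymorphic.
Raising α (making individual probes easier to reject) or raising
`min_fraction` can only shrink the analyzable set; this monotonicity is
property-tested. For same-background comparisons `all_analyzable_mask()`
skips the stage while keeping the pipeline shape.

## Stage 2 — calling nucleosome-position changes

Within each analyzable window a probe **qualifies** when

* the nucleosomal-channel genotype difference is significant (*p* ≤ α), and
* the reference-channel difference is not (*p* > α), and
* both tests are testable.

Calls are **maximal runs of consecutive qualifying probes** whose
probe-interval union spans at least `min_span` = 140 bp. "Consecutive" means
start-to-start distance at most `max_gap`, which defaults to the layout step:
with the default 50-bp/50-bp probe geometry a missing tile breaks a run, and
three adjacent 50-bp probes (150 bp) are the smallest callable region —
which is why the default geometry was chosen to make the 140-bp rule
correspond to ≥ 3 probes. The 140 bp are read as the *span of the probe
union* (first probe start to last probe end), not genomic distance between
run endpoints; with end-to-end tiling the two readings coincide.

Direction is assigned from the data, not from visual inspection: `gain` (of
a positioned nucleosome in the query genotype) iff the mean
query-minus-wild-type averaged-profile difference over the run probes is
positive. An exact zero is tie-broken as `loss` and flagged (`tie = TRUE`);
at float precision this is a measure-zero event but must not crash. Runs are
maximal and never merged across a disqualifying probe, so one locus can
yield `NP1`, `NP2`, ... named in 5′→3′ order. Swapping the genotype roles
flips every direction and changes nothing else — a property test.

The caller is verified against an independent brute-force oracle that
enumerates every contiguous probe run in a window, applies the dual
condition and span rule per run, and keeps maximal qualifying runs; on 1000
random 12-probe instances (including untestable probes) the two agree
exactly.

`arraywide_correlation` gives the global Pearson correlation of two
genotypes' averaged profiles over analyzable probes — the package-level
summary of how similar two chromatin landscapes are overall. Constant
input makes it undefined (`NA`), never an exception.

## Stage 3 — NOL classification

A nucleosome occupancy likelihood (NOL) track is a sequence-intrinsic
prediction of occupancy. For each call, the track is sampled (with linear
interpolation) at the probe midpoints of the call interval, optionally
widened by `flank` bp, and Pearson coefficients `r_wt` and `r_query` are
computed against the genotypes' averaged profiles over those probes. The
verdict is `mutant` iff `r_query > r_wt` strictly, `indeterminate` when
either coefficient is undefined or they differ by less than `tie_epsilon`
(default 1e-9 — exact ties are biologically meaningless but must be
handled). The verdict is invariant under positive affine transforms of the
track or either profile, and symmetric under swapping genotype labels.

Two statistical limits of this classification are worth stating plainly,
because they dictate how it should be used:

* **Span.** A default call contains only 3–5 probes. On so few points a
  flat profile's replicate noise routinely achieves |r| > 0.9 by chance, so
  region-only comparisons are close to coin flips whenever one genotype is
  featureless over the call. The `flank` argument widens the comparison
  span; with `flank = 200` (≈ 12 probes) the verdicts on shape-changing
  events become decisive and stable across seeds. The package default stays
  at `flank = 0` — the narrowest defensible reading of "the called region" —
  but analyses in this package's own tests and acceptance script use
  `flank = 200`, and we recommend users do the same.
* **Shape vs height.** Pearson correlation is scale-invariant, so an event
  that only rescales a peak (a partial loss that halves a nucleosome's
  height) produces profiles that are nearly affinely related — `r_wt` and
  `r_query` then differ by less than the noise and the verdict is
  uninformative. The classification is decisive for events that change the
  *shape* of the profile: gains of a nucleosome where none was, complete
  losses, and repositionings. Verdict-based conclusions should therefore be
  drawn from shape-changing calls.

## Stage 4 — qPCR quantification

MNase-qPCR protection at a locus is `2^-dCt` with `dCt = Ct(MNase) −
Ct(gDNA)`, normalized per sample to the same quantity at a control locus
with genotype-invariant nucleosome position (*Mwp1*); this
control-normalized `2^-dCt` is algebraically the same number as a `2^-ddCt`
with the control locus supplying the second delta. qRT-PCR expression is
`2^-ddCt` against a reference gene, with the calibrator genotype group's
mean dCt subtracted, so the calibrator's mean ddCt is 0 and its geometric
mean fold change is exactly 1 by construction. Technical replicates
(two per well by default) are averaged on the Ct scale before any delta —
standard practice. Amplification efficiency is fixed at 2 (the formulas
assume perfect per-cycle doubling); no standard-curve correction is
attempted. Group summaries are mean ± SD on the fold-change scale to mirror
conventional bar plots, with a log2-scale option, plus a two-sided pooled
*t* test when exactly two genotype groups are present. Plate offsets cancel:
adding a constant to all Ct values of one sample leaves `relative_np`
unchanged (property-tested).

## The synthetic generator

`simulate_experiment` builds complete experiments with recorded ground
truth. Its defaults are the study conditions: 400 windows × 3000 bp, 50-bp
probes at 50-bp steps (60 probes per window, 24000 probes), three replicate
pools per genotype, replicate noise SD 0.2 log2 units, ~10% polymorphic
windows, planted effect size Δ = 1 log2.

**Occupancy model.** Positioned nucleosomes are Gaussians: occupancy at
base *x* is `min(1, Σ h_j exp(−(x − c_j)² / 2σ_j²))` with σ = 30 bp
(footprint ≈ 150 bp, the DNA content of a nucleosome core), heights drawn
from U(0.7, 1), centers every ~200 bp with ±20 bp jitter, and a
nucleosome-free region within 80 bp of the TSS. The probe-level nucleosomal
signal is `log2(mean occupancy over the probe × dynamic_range +
occupancy_floor)` plus independent N(0, noise_sd) per replicate. The floor
(default 0.02) represents linker-level MNase background and sets the
signal's dynamic range (about −5.6 to 0 log2 units).

**Planted events.** A *loss* multiplies the affected nucleosome's height by
`2^-Δ`, so at zero noise the central probe drops by Δ attenuated by probe
averaging and the floor (this closed form is asserted in the tests). A
*gain* adds a positioned nucleosome of height `h̄ (2^Δ − 1)` — a full-height
nucleosome at Δ = 1 — at the planted interval's center; because a 147-bp
particle cannot fit in a 50-bp linker, the generator first removes one base
nucleosome from *every* genotype's configuration there, so the gain lands in
a genuinely open region and the genotypes stay identical outside planted
intervals. A *shift* is a loss plus an adjacent gain, with the displaced
neighbor removed from both genotypes to make room; recovery scoring counts a
shift as found if either part is. A planted *polymorphism* covers the
central 80% of its window and shifts the baseline of **both** channels by
the divergence effect (default 2 log2 units) in genotypes whose haplotype
differs from the reference haplotype — so a clear majority of the window's
probes diverges on the reference channel and the filter masks it, while NP
changes perturb only the nucleosomal channel.

**NOL.** The simulated track is the occupancy profile of a designated
"sequence-favored" genotype configuration (by default the query genotype,
emulating mutants that relax toward sequence-directed positioning), sampled
every 10 bp, optionally blended with smooth interpolated noise
(`distortion`).

**Ct tables.** `Ct = 20 − log2(quantity) + N(0, noise_sd)` per well, two
technical replicates; halving a template quantity costs exactly one cycle at
zero noise. Design helpers lay out the MNase-protection assay (target +
*Mwp1*, MNase + gDNA templates) and the expression assay (target +
reference gene).

Everything is deterministic given one integer seed: each generator derives
an independent sub-stream seed from the base seed and its own labels, so
`simulate_signals` for a given genotype returns the same values regardless
of call order, and the caller's RNG state is restored afterwards.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-specific hybridization efficiency and GC
bias, MNase sequence preference, saturation at high copy number, spatial
correlation of array noise, partial-penetrance genotypes, and real SNP/indel
structure (polymorphisms are block-shaped baseline offsets). Recovery rates
measured here are an upper bound on what identically parameterized real
experiments would achieve.

## Calibration and test scales

The suite's behavioural guarantees run at these sizes (chosen as the
smallest scales at which the properties are meaningful):

* oracle equivalence: 1000 random 12-probe windows, n = 3 per genotype;
* null calibration: two no-change genotypes at full scale (400 windows,
  24000 probes), per-probe rejection within the 99% binomial band around
  α = 0.05 and single-digit false calls (expected ≈ (α(1−α))³ per interior
  probe ≈ 2.5 array-wide);
* planted-change recovery: Δ = 1, 200-bp gains/losses in 50 of 400 windows,
  noise 0.2, n = 3. A one-time ten-run calibration at exactly these
  conditions gave sensitivity 0.74–0.96 (mean 0.87), precision ≥ 0.885, and
  direction accuracy 1.0 in every run; the frozen test thresholds
  (sensitivity ≥ 0.70, precision ≥ 0.80, direction accuracy ≥ 0.95) sit
  below those ranges. The main sensitivity ceiling is the reference-channel
  condition itself: each probe of a run must independently stay
  non-significant on the reference channel, so a 3-probe run survives that
  control with probability 0.95³ ≈ 0.86 — the price of the polymorphism
  guard, not a defect;
* polymorphism filter: 36 strongly divergent windows among 400 must be
  masked exactly, retaining 364;
* NOL classification: gains-only experiments (shape-changing events, for
  the reasons above), `flank = 200`, both track orientations must classify
  every call toward the matching genotype;
* qPCR: exact closed forms at zero noise and Monte-Carlo recovery of
  planted 2-fold changes over 100 simulations at noise 0.1.

## Known limitations

* The caller is deliberately the run-of-significant-probes procedure — no
  HMM or changepoint segmentation — so its resolution is the probe step and
  its power profile is set by α and the 140-bp rule.
* Partial (height-scaling) losses are invisible to the NOL verdict, as
  discussed above.
* The polymorphism filter infers comparability purely from hybridization
  signal; it cannot distinguish a dense SNP cluster from a genuine
  full-window occupancy difference on the reference channel.
* Efficiency-uncorrected ddCt assumes perfect doubling; strongly divergent
  primer efficiencies would bias fold changes.
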