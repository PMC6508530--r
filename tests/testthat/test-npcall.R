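test_that("comparing a genotype against itself yields zero calls", {
  withr::local_seed(21)
  lay <- tiny_layout(3, 12)
  nuc <- flat_signals(lay, noise_sd = 0.2, channel = "nucleosomal")
  ref <- flat_signals(lay, noise_sd = 0.2)
  calls <- call_np_changes(nuc, nuc, ref, ref, lay)
  expect_equal(nrow(calls), 0)
})

test_that("a zero-noise planted loss is called once, as a loss, over the planted interval", {
  lay <- simulate_layout(5, seed = 30)
  truth <- simulate_truth(lay, n_changes = 1, change_kinds = "loss", delta = 1,
                          n_polymorphic = 0, noise_sd = 0, seed = 30)
  # zero-noise replicate columns are identical, so add minuscule jitter to
  # make variances nonzero without moving any mean visibly
  jitter_sig <- function(s, seed) {
    withr::with_seed(seed, {
      s$nucleosomal$values <- s$nucleosomal$values +
        matrix(rnorm(length(s$nucleosomal$values), 0, 1e-3), nrow(s$nucleosomal$values))
      s$reference$values <- s$reference$values +
        matrix(rnorm(length(s$reference$values), 0, 1e-3), nrow(s$reference$values))
    })
    s
  }
  wt <- jitter_sig(simulate_signals(lay, truth, "wild_type"), 1)
  mut <- jitter_sig(simulate_signals(lay, truth, "mutant"), 2)
  calls <- call_np_changes(wt$nucleosomal, mut$nucleosomal,
                           wt$reference, mut$reference, lay)
  ch <- truth$planted_changes
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "loss")
  expect_equal(calls$window_id, ch$window_id)
  # the call covers the planted interval's core
  expect_lte(calls$start, ch$start + 50)
  expect_gte(calls$end, ch$end - 50)
  expect_gte(calls$span_bp, 140)
})

test_that("changes spanning fewer than 140 bp of probes are not called", {
  withr::local_seed(31)
  lay <- tiny_layout(1, 12)
  np <- n_probes(lay)
  wt_n <- matrix(rnorm(np * 3, 0, 0.1), np)
  q_n <- wt_n + matrix(rnorm(np * 3, 0, 0.1), np)
  q_n[5:6, ] <- q_n[5:6, ] + 5    # exactly two probes = 100 bp span
  refm <- make_signals(lay, matrix(rnorm(np * 3, 0, 0.1), np), channel = "reference")
  calls <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                           refm, refm, lay)
  expect_equal(nrow(calls), 0)
  # a third adjacent probe reaches 150 bp and the region is called
  q_n[7, ] <- q_n[7, ] + 5
  calls3 <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                            refm, refm, lay)
  expect_equal(nrow(calls3), 1)
  expect_equal(calls3$span_bp, 150)
  expect_equal(calls3$n_probes, 3L)
  expect_equal(calls3$direction, "gain")
})

test_that("calls never land in windows masked as polymorphic", {
  withr::local_seed(32)
  lay <- tiny_layout(4, 12)
  np <- n_probes(lay)
  wt_n <- matrix(rnorm(np * 3, 0, 0.1), np)
  q_n <- wt_n + matrix(rnorm(np * 3, 0, 0.1), np)
  q_n[c(3:6, 15:18, 27:30), ] <- q_n[c(3:6, 15:18, 27:30), ] + 5  # windows 1-3
  refa <- matrix(rnorm(np * 3, 0, 0.1), np)
  refb <- refa
  refb[13:24, ] <- refb[13:24, ] + 5   # window 2 divergent gDNA
  wt_ref <- make_signals(lay, refa, channel = "reference")
  q_ref <- make_signals(lay, refb, channel = "reference")
  mask <- filter_polymorphic(wt_ref, q_ref, lay)
  expect_equal(analyzable_windows(mask), c("w1", "w3", "w4"))
  calls <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                           wt_ref, q_ref, lay, mask = mask)
  expect_setequal(calls$window_id, c("w1", "w3"))
})

test_that("probes failing the reference-channel condition split runs", {
  withr::local_seed(33)
  lay <- tiny_layout(1, 12)
  np <- n_probes(lay)
  wt_n <- matrix(rnorm(np * 3, 0, 0.05), np)
  q_n <- wt_n + matrix(rnorm(np * 3, 0, 0.05), np)
  q_n[3:10, ] <- q_n[3:10, ] + 5          # 8-probe nucleosomal difference
  refa <- matrix(rnorm(np * 3, 0, 0.05), np)
  refb <- refa
  refb[6, ] <- refb[6, ] + 5              # gDNA difference at probe 6 only
  calls <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                           make_signals(lay, refa, channel = "reference"),
                           make_signals(lay, refb, channel = "reference"), lay)
  # probes 3:5 (150 bp) and 7:10 (200 bp) become separate calls NP1/NP2
  expect_equal(nrow(calls), 2)
  expect_equal(calls$call_name, c("g1_NP1", "g1_NP2"))
  expect_equal(calls$n_probes, c(3L, 4L))
  expect_true(calls$end[1] < calls$start[2])
})

test_that("swapping wild type and query flips every direction and nothing else", {
  ex <- simulate_experiment(n_windows = 20, n_changes = 6, n_polymorphic = 0, seed = 34)
  s <- ex$signals
  fwd <- call_np_changes(s$wild_type$nucleosomal, s$mutant$nucleosomal,
                         s$wild_type$reference, s$mutant$reference, ex$layout)
  rev <- call_np_changes(s$mutant$nucleosomal, s$wild_type$nucleosomal,
                         s$mutant$reference, s$wild_type$reference, ex$layout)
  expect_gt(nrow(fwd), 0)
  expect_equal(rev$window_id, fwd$window_id)
  expect_equal(rev$start, fwd$start)
  expect_equal(rev$end, fwd$end)
  expect_equal(rev$direction, ifelse(fwd$direction == "gain", "loss", "gain"))
  expect_equal(rev$mean_delta, -fwd$mean_delta)
})

test_that("call_np_changes equals the exhaustive run-enumeration oracle on random instances", {
  withr::local_seed(35)
  lay <- tiny_layout(1, 12)
  for (i in 1:60) {
    inst <- random_instance(lay)
    got <- call_np_changes(inst$wt_nuc, inst$q_nuc, inst$wt_ref, inst$q_ref, lay)
    want <- oracle_np_calls(inst$wt_nuc, inst$q_nuc, inst$wt_ref, inst$q_ref, lay)
    expect_equal(as.data.frame(got)[c("window_id", "start", "end")], want,
                 ignore_attr = TRUE)
  }
})

test_that("runs do not jump across tiling holes wider than max_gap", {
  # hand-built layout with a missing tile between probes 3 and 4
  w <- data.frame(window_id = "w1", gene_id = "g1", chrom = "chrT",
                  start = 1L, end = 3000L, tss_offset = 1500L, strand = "+")
  starts <- c(1L, 51L, 101L, 201L, 251L, 301L)  # hole at 151-200
  p <- data.frame(probe_id = sprintf("p%d", 1:6), window_id = "w1",
                  start = starts, end = starts + 49L)
  lay <- probe_layout(w, p, probe_length = 50L, step = 50L)
  withr::local_seed(36)
  np <- 6L
  wt_n <- matrix(rnorm(np * 3, 0, 0.05), np)
  q_n <- wt_n + matrix(rnorm(np * 3, 0, 0.05), np) + 5  # all probes shifted
  refm <- make_signals(lay, matrix(rnorm(np * 3, 0, 0.05), np), channel = "reference")
  calls <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                           refm, refm, lay)
  # default max_gap = step: the hole splits one qualifying stretch in two
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start, c(1L, 201L))
  # a permissive max_gap bridges it
  calls_b <- call_np_changes(make_signals(lay, wt_n), make_signals(lay, q_n),
                             refm, refm, lay, max_gap = 100L)
  expect_equal(nrow(calls_b), 1)
  expect_equal(calls_b$span_bp, 350L)
})

test_that("direction classification follows the sign of the mean profile difference", {
  lay <- tiny_layout(1, 4)
  wt <- setNames(c(0, 0, 0, 0), lay$probes$probe_id)
  up <- classify_direction(names(wt)[1:2], wt, wt + 1)
  expect_equal(up$direction, "gain")
  down <- classify_direction(names(wt)[1:2], wt, wt - 1)
  expect_equal(down$direction, "loss")
  mixed <- classify_direction(names(wt), wt, setNames(c(-1, 2, -1, 1), names(wt)))
  expect_equal(mixed$direction, "gain")  # mean +0.25
  tie <- classify_direction(names(wt)[1:2], wt, setNames(c(-1, 1, 0, 0), names(wt)))
  expect_equal(tie$direction, "loss")
  expect_true(tie$tie)
  expect_error(classify_direction(character(0), wt, wt), "empty")
})

test_that("array-wide correlation behaves like Pearson r with NA guards", {
  a <- c(1, 2, 3, 5, 4)
  expect_equal(arraywide_correlation(a, a), 1)
  expect_equal(arraywide_correlation(a, -a), -1)
  expect_equal(arraywide_correlation(a, 2 * a + 3), 1)
  b <- c(2, 1, 4, 3, 6)
  expect_equal(arraywide_correlation(a, b), cor(a, b))
  expect_true(is.na(arraywide_correlation(a, rep(1, 5))))
  expect_error(arraywide_correlation(a, b[1:3]), "equal length")
  # NA pairs dropped
  b2 <- b; b2[2] <- NA
  expect_equal(arraywide_correlation(a, b2), cor(a[-2], b[-2]))
})

test_that("calls written to TSV read back with identical fields", {
  ex <- simulate_experiment(n_windows = 15, n_changes = 5, n_polymorphic = 0, seed = 37)
  s <- ex$signals
  calls <- call_np_changes(s$wild_type$nucleosomal, s$mutant$nucleosomal,
                           s$wild_type$reference, s$mutant$reference, ex$layout)
  expect_gt(nrow(calls), 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_np_calls(calls, f)
  back <- read_np_calls(f)
  expect_equal(back$call_name, calls$call_name)
  expect_equal(back$start, calls$start)
  expect_equal(back$direction, calls$direction)
  expect_equal(back$mean_delta, calls$mean_delta, tolerance = 1e-12)
})
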