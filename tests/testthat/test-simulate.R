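test_that("occupancy follows the clamped Gaussian-sum model", {
  lay <- tiny_layout(1, 6)
  truth <- simulate_truth(lay, n_changes = 0, n_polymorphic = 0, seed = 1)
  # strip all nucleosomes -> occupancy identically zero
  empty <- truth
  empty$nucleosomes <- lapply(empty$nucleosomes, function(x) x[0, ])
  expect_true(all(simulate_occupancy(empty, lay, "wild_type", "w1") == 0))

  # a single unit nucleosome peaks at exactly 1 at its center
  one <- truth
  for (g in names(one$nucleosomes))
    one$nucleosomes[[g]] <- data.frame(window_id = "w1", center = 1500,
                                       sd = 30, height = 1)
  expect_equal(simulate_occupancy(one, lay, "wild_type", "w1", pos = 1500), 1)
  expect_equal(simulate_occupancy(one, lay, "wild_type", "w1", pos = 1530),
               exp(-30^2 / (2 * 30^2)))

  # two overlapping nucleosomes sum then clamp at 1
  two <- truth
  for (g in names(two$nucleosomes))
    two$nucleosomes[[g]] <- data.frame(window_id = "w1", center = c(1480, 1520),
                                       sd = 30, height = 0.8)
  pos <- 1460:1540
  raw <- 0.8 * exp(-(pos - 1480)^2 / 1800) + 0.8 * exp(-(pos - 1520)^2 / 1800)
  expect_equal(simulate_occupancy(two, lay, "wild_type", "w1", pos = pos),
               pmin(raw, 1))
  expect_true(any(raw > 1))  # the clamp is actually exercised here

  expect_error(simulate_occupancy(truth, lay, "nope", "w1"), "unknown genotype")
})

test_that("generators are deterministic and zero-noise genotypes with equal truth coincide", {
  lay <- simulate_layout(6, seed = 2)
  t1 <- simulate_truth(lay, n_changes = 0, n_polymorphic = 0, noise_sd = 0, seed = 5)
  t2 <- simulate_truth(lay, n_changes = 0, n_polymorphic = 0, noise_sd = 0, seed = 5)
  expect_identical(t1, t2)

  s_wt <- simulate_signals(lay, t1, "wild_type")
  s_mut <- simulate_signals(lay, t1, "mutant")
  # no planted changes, no noise: the two genotypes are bit-identical
  expect_identical(s_wt$nucleosomal$values, s_mut$nucleosomal$values)
  expect_identical(s_wt$reference$values, s_mut$reference$values)

  # determinism regardless of call order
  again <- simulate_signals(lay, t1, "wild_type")
  expect_identical(again$nucleosomal$values, s_wt$nucleosomal$values)
})

test_that("planted changes perturb only the nucleosomal channel, polymorphisms both", {
  lay <- simulate_layout(12, seed = 3)
  truth <- simulate_truth(lay, n_changes = 4, n_polymorphic = 3,
                          noise_sd = 0, seed = 3)
  wt <- simulate_signals(lay, truth, "wild_type")
  mut <- simulate_signals(lay, truth, "mutant")
  p <- lay$probes
  poly <- truth$planted_polymorphisms
  in_poly <- rep(FALSE, n_probes(lay))
  for (r in seq_len(nrow(poly)))
    in_poly <- in_poly | (p$window_id == poly$window_id[r] &
                          p$midpoint >= poly$start[r] & p$midpoint <= poly$end[r])
  dref <- mut$reference$values[, 1] - wt$reference$values[, 1]
  # reference channel differs exactly on polymorphic probes, by the effect size
  expect_equal(unname(dref[in_poly]), rep(2, sum(in_poly)))
  expect_true(all(dref[!in_poly] == 0))

  # nucleosomal channel differs only inside planted change or polymorphic windows
  dnuc <- mut$nucleosomal$values[, 1] - wt$nucleosomal$values[, 1]
  touched <- p$window_id %in% c(truth$planted_changes$window_id, poly$window_id)
  expect_true(all(dnuc[!touched] == 0))
  expect_true(any(dnuc != 0))
})

test_that("a planted loss lowers the probe signal by about delta after probe averaging", {
  lay <- simulate_layout(8, seed = 4)
  truth <- simulate_truth(lay, n_changes = 4, change_kinds = "loss", delta = 1,
                          n_polymorphic = 0, noise_sd = 0, seed = 4)
  wt <- simulate_signals(lay, truth, "wild_type")
  mut <- simulate_signals(lay, truth, "mutant")
  d <- mut$nucleosomal$values[, 1] - wt$nucleosomal$values[, 1]
  p <- lay$probes
  ch <- truth$planted_changes
  for (i in seq_len(nrow(ch))) {
    center <- (ch$start[i] + ch$end[i]) / 2
    at <- which(p$window_id == ch$window_id[i] & abs(p$midpoint - center) <= 25)
    # the central probe drops by delta, attenuated by probe averaging and
    # the occupancy floor: within [-delta, -0.8 * delta]
    expect_true(all(d[at] < -0.8 & d[at] >= -1))
  }
})

test_that("a distortion-free NOL track equals the reference configuration's occupancy", {
  lay <- simulate_layout(4, seed = 6)
  truth <- simulate_truth(lay, n_changes = 2, n_polymorphic = 0, seed = 6)
  nol <- simulate_nol(lay, truth, reference_genotype = "mutant", distortion = 0)
  w <- lay$windows[2, ]
  pos <- seq(w$start, w$end, by = 10)
  expect_equal(nol_at(nol, w$chrom, pos),
               simulate_occupancy(truth, lay, "mutant", w$window_id, pos = pos))
})

test_that("simulated Ct tables obey the one-cycle-per-doubling model", {
  des <- data.frame(target = "T", sample_id = c("s1", "s2"), genotype = "g",
                    assay = "gdna", quantity = c(1, 0.5))
  ct <- simulate_ct(des, noise_sd = 0, seed = 1)
  m <- tapply(ct$ct, ct$sample_id, mean)
  expect_equal(unname(m["s2"] - m["s1"]), 1)  # halving costs one cycle
  expect_equal(sum(ct$sample_id == "s1"), 2)  # two technical replicates

  expect_error(simulate_ct(transform(des, quantity = c(1, 0)), seed = 1),
               "positive")
  # determinism
  expect_identical(simulate_ct(des, noise_sd = 0.3, seed = 9),
                   simulate_ct(des, noise_sd = 0.3, seed = 9))
})

test_that("full experiments are reproducible end to end under one seed", {
  a <- simulate_experiment(n_windows = 10, n_changes = 2, n_polymorphic = 2, seed = 77)
  b <- simulate_experiment(n_windows = 10, n_changes = 2, n_polymorphic = 2, seed = 77)
  expect_identical(a$truth, b$truth)
  expect_identical(a$signals$mutant$nucleosomal$values,
                   b$signals$mutant$nucleosomal$values)
  expect_identical(as.data.frame(a$nol), as.data.frame(b$nol))
})
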