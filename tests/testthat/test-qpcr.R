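# hand-built Ct tables with known delta structure
np_ct_fixture <- function(target_mnase_wt = 20, target_mnase_mut = 20,
                          n = 2) {
  rows <- list()
  add <- function(target, sample, genotype, assay, ct) {
    for (tr in seq_len(n))
      rows[[length(rows) + 1L]] <<- data.frame(
        target = target, sample_id = sample, genotype = genotype,
        assay = assay, tech_rep = tr, ct = ct, stringsAsFactors = FALSE)
  }
  for (s in 1:3) {
    add("Stc1_NP1", paste0("wt", s), "wild_type", "mnase", target_mnase_wt)
    add("Stc1_NP1", paste0("wt", s), "wild_type", "gdna", 20)
    add("Mwp1", paste0("wt", s), "wild_type", "mnase", 21)
    add("Mwp1", paste0("wt", s), "wild_type", "gdna", 21)
    add("Stc1_NP1", paste0("m", s), "mutant", "mnase", target_mnase_mut)
    add("Stc1_NP1", paste0("m", s), "mutant", "gdna", 20)
    add("Mwp1", paste0("m", s), "mutant", "mnase", 21)
    add("Mwp1", paste0("m", s), "mutant", "gdna", 21)
  }
  ct_table(do.call(rbind, rows))
}

test_that("relative NP closed forms: zero delta gives 1, one cycle gives 0.5", {
  r <- relative_np(np_ct_fixture(), "Stc1_NP1")
  expect_equal(r$samples$relative_np, rep(1, 6))
  expect_equal(r$groups$mean, c(1, 1))
  expect_equal(r$groups$sd, c(0, 0))

  # target loses one cycle of protection in the mutant: ratio 0.5 exactly
  r2 <- relative_np(np_ct_fixture(target_mnase_mut = 21), "Stc1_NP1")
  expect_equal(r2$groups$mean[r2$groups$genotype == "wild_type"], 1)
  expect_equal(r2$groups$mean[r2$groups$genotype == "mutant"], 0.5)
})

test_that("relative NP is invariant to per-sample plate offsets", {
  ct <- np_ct_fixture(target_mnase_mut = 21)
  shifted <- as.data.frame(ct)
  shifted$ct[shifted$sample_id == "m1"] <- shifted$ct[shifted$sample_id == "m1"] + 3
  r0 <- relative_np(ct, "Stc1_NP1")
  r1 <- relative_np(ct_table(shifted), "Stc1_NP1")
  expect_equal(r1$samples$relative_np, r0$samples$relative_np)
})

test_that("raising the target MNase Ct strictly lowers relative NP", {
  vals <- vapply(c(20, 20.5, 21, 22), function(ctm)
    relative_np(np_ct_fixture(target_mnase_mut = ctm),
                "Stc1_NP1")$groups$mean[2], numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("missing assays are reported by name", {
  ct <- np_ct_fixture()
  no_gdna <- ct_table(as.data.frame(ct)[!(ct$target == "Stc1_NP1" &
                                          ct$assay == "gdna"), ])
  expect_error(relative_np(no_gdna, "Stc1_NP1"), "gdna")
  expect_error(relative_np(ct, "Stc1_NP1", control_locus = "Nope"), "Nope")
})

expr_ct_fixture <- function(mut_dct_shift = 0) {
  rows <- list()
  for (s in 1:3) {
    for (g in c("wild_type", "mutant")) {
      sid <- paste0(substr(g, 1, 1), s)
      shift <- if (g == "mutant") mut_dct_shift else 0
      rows[[length(rows) + 1L]] <- data.frame(
        target = c("Chr106", "UbiConj"), sample_id = sid, genotype = g,
        assay = "cdna", tech_rep = 1L,
        ct = c(22 + shift, 18), stringsAsFactors = FALSE)
    }
  }
  ct_table(do.call(rbind, rows))
}

test_that("ddCt closed forms: identical samples give fold 1, one extra cycle gives 0.5", {
  r <- relative_expression(expr_ct_fixture(0), "Chr106", "UbiConj", "wild_type")
  expect_equal(r$samples$fold, rep(1, 6))
  r2 <- relative_expression(expr_ct_fixture(1), "Chr106", "UbiConj", "wild_type")
  expect_equal(r2$groups$mean[r2$groups$genotype == "mutant"], 0.5)
  expect_error(relative_expression(expr_ct_fixture(), "Chr106", "UbiConj", "Nope"),
               "no samples")
})

test_that("the calibrator group's mean fold change is 1 for arbitrary inputs", {
  withr::local_seed(51)
  for (i in 1:10) {
    ct <- expr_ct_fixture(runif(1, -2, 2))
    noisy <- as.data.frame(ct)
    noisy$ct <- noisy$ct + rnorm(nrow(noisy), 0, 0.5)
    r <- relative_expression(ct_table(noisy), "Chr106", "UbiConj", "wild_type")
    expect_equal(2^mean(log2(r$samples$fold[r$samples$genotype == "wild_type"])),
                 1, tolerance = 1e-12)
    expect_equal(mean(r$samples$ddct[r$samples$genotype == "wild_type"]), 0,
                 tolerance = 1e-12)
  }
})

test_that("technical replicates are averaged on the Ct scale before deltas", {
  ct <- np_ct_fixture()
  d <- as.data.frame(ct)
  # unbalanced tech reps averaging to the same mean must not change results
  extra <- d[d$sample_id == "wt1" & d$assay == "mnase" & d$tech_rep == 1, ]
  extra$tech_rep <- 3L
  extra$ct <- extra$ct  # same value, mean unchanged
  r <- relative_np(ct_table(rbind(d, extra)), "Stc1_NP1")
  expect_equal(r$samples$relative_np, rep(1, 6))
})

test_that("simulated 2-fold changes are recovered through the published formulas", {
  # zero noise: exact recovery
  ct0 <- simulate_ct(expression_design(fold = 2), noise_sd = 0, seed = 3)
  r0 <- relative_expression(ct0, "Chr106", "UbiConj", "wild_type")
  expect_equal(r0$groups$mean[r0$groups$genotype == "mutant"], 2)

  ctn <- simulate_ct(mnase_qpcr_design(protection_ratio = 0.5), noise_sd = 0,
                     seed = 4)
  rn <- relative_np(ctn, "Stc1_NP1")
  expect_equal(rn$groups$mean[rn$groups$genotype == "mutant"], 0.5)

  # Monte Carlo at noise_sd = 0.1: mean over runs close to the planted fold
  folds <- vapply(1:50, function(i) {
    ct <- simulate_ct(expression_design(fold = 0.5), noise_sd = 0.1, seed = 100 + i)
    r <- relative_expression(ct, "Chr106", "UbiConj", "wild_type")
    r$groups$mean[r$groups$genotype == "mutant"]
  }, numeric(1))
  expect_equal(mean(folds), 0.5, tolerance = 0.05)
})

test_that("Ct tables round-trip through CSV", {
  ct <- np_ct_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_ct_csv(ct, f)
  back <- read_ct_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(ct))
})
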