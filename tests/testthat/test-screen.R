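stage7 <- default_stage_grid()

series_df <- function(tpm) data.frame(stage = names(stage7), tpm = tpm)

test_that("classify_trigger_pattern reproduces hand-evaluated verdicts", {
  # flat: fails the trigger-stage increase
  flat <- classify_trigger_pattern(series_df(rep(10, 7)))
  expect_false(flat$verdict)
  expect_equal(flat$failing, "trigger-stage increase")
  # unchanged then doubling at shield and sustained: trigger
  up <- classify_trigger_pattern(series_df(c(10, 10, 10, 20, 25, 30, 30)))
  expect_true(up$verdict)
  expect_equal(up$failing, "")
  # monotone decreasing: fails the pre-window unchanged rule
  down <- classify_trigger_pattern(series_df(c(30, 20, 10, 5, 5, 5, 5)))
  expect_false(down$verdict)
  expect_equal(down$failing, "pre-window unchanged")
  # rise not sustained
  spike <- classify_trigger_pattern(series_df(c(10, 10, 10, 30, 5, 5, 5)))
  expect_false(spike$verdict)
  expect_equal(spike$failing, "sustained")
})

test_that("missing stages and zero genes are reported", {
  short <- data.frame(stage = names(stage7)[-4],
                      tpm = rep(10, 6))
  expect_error(classify_trigger_pattern(short), "shield")
  zero <- classify_trigger_pattern(series_df(rep(0, 7)),
                                   screen_criteria(pseudocount = 0))
  expect_false(zero$verdict)
  expect_equal(zero$failing, "below detection")
})

make_panels <- function(n_genes = 100, planted = 1:10, noise = 0,
                        seed = 11) {
  spec <- sim_expression_spec(n_genes = n_genes,
                              planted_triggers = planted,
                              noise_cv = noise, seed = seed)
  espec <- spec
  espec$conditions <- "embryo"
  list(explant = gen_expression_panel(spec),
       embryo = gen_expression_panel(espec),
       planted = sprintf("g%04d", sort(unique(planted))))
}

test_that("tiers equal the planted set on noiseless panels and are nested", {
  p <- make_panels()
  cs <- run_screen(list(p$explant), p$embryo, screen_criteria())
  expect_setequal(cs$tier1, p$planted)
  # planted Delta = 2.0 and TPM well above 5: tiers collapse onto tier 1
  expect_setequal(cs$tier2, cs$tier1)
  expect_setequal(cs$tier3, cs$tier1)
  expect_true(all(cs$tier3 %in% cs$tier2) && all(cs$tier2 %in% cs$tier1))
})

test_that("an infinite TPM filter empties tier 3", {
  p <- make_panels()
  cs <- run_screen(list(p$explant), p$embryo,
                   screen_criteria(tpm_min = Inf))
  expect_length(cs$tier3, 0)
  expect_gt(length(cs$tier2), 0)
})

test_that("tier nesting holds on noisy panels too", {
  p <- make_panels(noise = 0.4, seed = 21)
  cs <- run_screen(list(p$explant), p$embryo, screen_criteria())
  expect_true(all(cs$tier2 %in% cs$tier1))
  expect_true(all(cs$tier3 %in% cs$tier2))
  expect_true(all(diff(cs$counts) <= 0))
})

test_that("fold-only screen is invariant to gene order and global rescaling", {
  p <- make_panels(n_genes = 40, planted = c(2, 8, 31))
  cs0 <- run_screen(list(p$explant), p$embryo, screen_criteria())
  shuffled <- p$explant[rev(seq_len(nrow(p$explant))), ]
  cs1 <- run_screen(list(shuffled), p$embryo, screen_criteria())
  expect_setequal(cs0$tier1, cs1$tier1)
  scaled <- p$explant
  scaled$tpm <- scaled$tpm * 37.5
  # pseudocount off so rescaling is exact
  crit0 <- screen_criteria(pseudocount = 0)
  expect_setequal(run_screen(list(scaled), p$embryo, crit0)$tier1,
                  run_screen(list(p$explant), p$embryo, crit0)$tier1)
})

test_that("disjoint gene universes are rejected, overlap is intersected", {
  p <- make_panels(n_genes = 20, planted = 1:2)
  other <- p$embryo
  other$gene <- sub("^g", "h", other$gene)
  expect_error(run_screen(list(p$explant), other, screen_criteria()),
               "disjoint")
  # partial overlap: dropped ids are counted
  half <- p$embryo[p$embryo$gene %in% sprintf("g%04d", 1:10), ]
  cs <- run_screen(list(p$explant), half, screen_criteria())
  expect_equal(cs$dropped_genes, 10)
})

test_that("replicate-test mode rejects noise-only increases", {
  p <- make_panels(n_genes = 60, planted = 1:6, noise = 0.2, seed = 31)
  crit <- screen_criteria(significance_mode = "replicate_test",
                          alpha = 0.05)
  cs <- run_screen(list(p$explant), p$embryo, crit)
  # every call must still satisfy the fold criteria
  fold_only <- run_screen(list(p$explant), p$embryo, screen_criteria())
  expect_true(all(cs$tier1 %in% fold_only$tier1))
})

test_that("ratio trajectory matches hand arithmetic", {
  sh <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  df <- data.frame(gene = rep(c("num", "den"), each = 4),
                   stage = rep(names(sh), 2), hpf = rep(unname(sh), 2),
                   condition = "x", replicate = 1,
                   tpm = c(1, 2, 8, 6, 8, 8, 4, 2))
  rt <- ratio_trajectory(expression_panel(df, sh), "num", "den",
                         pseudocount = 0)
  expect_equal(rt$trajectory$ratio, c(0.125, 0.25, 2, 3))
  expect_equal(rt$peak_stage, "s4")
  # crossing of 1 between s2 (0.25) and s3 (2): 2 + 0.75/1.75
  expect_equal(rt$inversion_hpf, 2 + 0.75 / 1.75, tolerance = 1e-12)
  expect_equal(rt$trajectory$fc_numerator, c(1, 2, 8, 6))
})

test_that("identical genes give a flat ratio with no inversion", {
  sh <- c(s1 = 1, s2 = 2, s3 = 3)
  df <- data.frame(gene = rep(c("a", "b"), each = 3),
                   stage = rep(names(sh), 2), hpf = rep(unname(sh), 2),
                   condition = "x", replicate = 1, tpm = rep(c(5, 7, 9), 2))
  rt <- ratio_trajectory(expression_panel(df, sh), "a", "b")
  expect_equal(rt$trajectory$ratio, rep(1, 3))
  expect_true(is.na(rt$inversion_hpf))
  expect_equal(rt$peak_stage, "s1")  # earliest-stage tie rule
})

test_that("all-zero denominators are rejected", {
  sh <- c(s1 = 1, s2 = 2)
  df <- data.frame(gene = rep(c("a", "b"), each = 2),
                   stage = rep(names(sh), 2), hpf = rep(unname(sh), 2),
                   condition = "x", replicate = 1, tpm = c(1, 2, 0, 0))
  expect_error(ratio_trajectory(expression_panel(df, sh), "a", "b"),
               "ratio undefined")
  expect_error(ratio_trajectory(expression_panel(df, sh), "a", "zzz"),
               "zzz")
})

test_that("a planted sumf2/sumf1-style inversion is localized correctly", {
  # numerator switched on at shield while the denominator decays:
  # the ratio must peak after gastrulation onset and invert before it
  sh <- default_stage_grid()
  num <- c(2, 2, 2, 20, 20, 18, 16)        # trigger-like
  den <- c(40, 30, 18, 10, 12, 14, 16)     # maternal decay, late recovery
  df <- data.frame(gene = rep(c("sumf2", "sumf1"), each = 7),
                   stage = rep(names(sh), 2), hpf = rep(unname(sh), 2),
                   condition = "explant", replicate = 1, tpm = c(num, den))
  rt <- ratio_trajectory(expression_panel(df, sh), "sumf2", "sumf1",
                         pseudocount = 0)
  expect_equal(rt$peak_stage, "shield")
  expect_true(rt$inversion_hpf > 5.3 && rt$inversion_hpf <= 6.0)
})
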