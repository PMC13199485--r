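test_that("ddCt matches the worked example and identities", {
  ct <- data.frame(sample = rep(c("treated", "cal"), each = 2),
                   gene = rep(c("tgt", "ref"), 2),
                   ct = c(25, 20, 24, 20))
  res <- ddct(ct, "tgt", "ref", "cal")
  expect_equal(res$ddct[res$sample == "treated"], 1)
  expect_equal(res$fold_change[res$sample == "treated"], 0.5)
  # calibrator against itself is exactly 1
  expect_equal(res$fold_change[res$sample == "cal"], 1)
  # ddCt = -1 doubles expression
  ct2 <- data.frame(sample = rep(c("s", "cal"), each = 2),
                    gene = rep(c("tgt", "ref"), 2), ct = c(23, 20, 24, 20))
  expect_equal(ddct(ct2, "tgt", "ref", "cal")$fold_change[1], 2)
})

test_that("ddCt averages technical replicates before differencing", {
  ct <- data.frame(sample = rep("s", 6),
                   gene = rep(c("tgt", "ref"), each = 3),
                   ct = c(25.2, 24.8, 25.0, 20.1, 19.9, 20.0))
  cal <- data.frame(sample = "cal", gene = c("tgt", "ref"),
                    ct = c(24, 20))
  res <- ddct(rbind(ct, cal), "tgt", "ref", "cal")
  expect_equal(res$dct[res$sample == "s"], 5)
  expect_equal(res$ct_target_sd[res$sample == "s"], sd(c(25.2, 24.8, 25)))
  # non-finite rows are dropped with a warning
  expect_warning(ddct(rbind(ct, cal,
                            data.frame(sample = "s", gene = "tgt",
                                       ct = NA)),
                      "tgt", "ref", "cal"), "non-finite")
  expect_error(ddct(ct, "tgt", "missing", "s"), "missing")
})

test_that("disaccharide quantification follows the internal-standard arithmetic", {
  pk <- data.frame(code = c("D0A0", "D0S6", "D2S6", "D0S0"),
                   area_light = c(100, 50, 25, 25),
                   area_heavy = c(100, 100, 100, 100))
  res <- quantify_disaccharides(pk, standard_pmol = 20, protein_ug = 2)
  expect_equal(res$amount_pmol, c(20, 10, 5, 5))
  expect_equal(res$pmol_per_ug, c(10, 5, 2.5, 2.5))
  expect_equal(sum(res$percent), 100, tolerance = 1e-9)
  expect_equal(res$percent, c(50, 25, 12.5, 12.5))
})

test_that("disaccharide edge cases behave as specified", {
  one <- quantify_disaccharides(data.frame(code = "D2S6",
                                           area_light = 7,
                                           area_heavy = 3))
  expect_equal(one$percent, 100)
  four <- quantify_disaccharides(data.frame(code = c("D0A0", "D0S0",
                                                     "D0S6", "D2S6"),
                                            area_light = 5,
                                            area_heavy = 10))
  expect_equal(four$percent, rep(25, 4))
  # zero heavy channel flags the code, all-zero errors
  part <- quantify_disaccharides(data.frame(code = c("D0A0", "D0S6"),
                                            area_light = c(5, 5),
                                            area_heavy = c(10, 0)))
  expect_false(part$quantifiable[2])
  expect_true(is.na(part$amount_pmol[2]))
  expect_equal(part$percent[1], 100)
  expect_error(quantify_disaccharides(data.frame(code = "D0A0",
                                                 area_light = 5,
                                                 area_heavy = 0)),
               "no quantifiable")
  expect_warning(quantify_disaccharides(data.frame(code = "Q9Z9",
                                                   area_light = 1,
                                                   area_heavy = 1)),
                 "unknown")
})

test_that("disaccharide amounts are homogeneous in the light channel", {
  set.seed(5)
  pk <- data.frame(code = c("D0A0", "D0S0", "D0S6", "D2S6"),
                   area_light = runif(4, 1, 100),
                   area_heavy = runif(4, 50, 150))
  r1 <- quantify_disaccharides(pk)
  pk2 <- pk
  pk2$area_light <- pk2$area_light * 3.7
  r2 <- quantify_disaccharides(pk2)
  expect_equal(r2$amount_pmol, 3.7 * r1$amount_pmol, tolerance = 1e-12)
  expect_equal(r2$percent, r1$percent, tolerance = 1e-12)
})

test_that("identity and similarity match hand-scored examples", {
  same <- pairwise_identity_similarity("MKTAYIAK", "MKTAYIAK")
  expect_equal(same$identity, 100)
  expect_equal(same$similarity, 100)
  # E<->K scores 1 in BLOSUM62: similar but not identical
  st <- pairwise_identity_similarity("ACDE", "ACDK", prealigned = TRUE)
  expect_equal(st$identity, 75)
  expect_equal(st$similarity, 100)
  # D<->R scores -2: dissimilar
  st2 <- pairwise_identity_similarity("ACDE", "ACRE", prealigned = TRUE)
  expect_equal(st2$identity, 75)
  expect_equal(st2$similarity, 75)
})

test_that("gap columns obey the denominator policy", {
  st <- pairwise_identity_similarity("AC-DE", "ACWDE", prealigned = TRUE)
  expect_equal(st$identity, 100)           # 4 identical / 4 residue columns
  expect_equal(st$gap_count, 1)
  st2 <- pairwise_identity_similarity("AC-DE", "ACWDE", prealigned = TRUE,
                                      denominator = "any_residue")
  expect_equal(st2$identity, 80)           # 4 / 5 columns
})

test_that("sequence validation errors name the position", {
  expect_error(pairwise_identity_similarity("", "ACD"), "empty")
  expect_error(pairwise_identity_similarity("ACB", "ACD"),
               "`B` at position 3")
  # X is allowed and scores 0 (not similar, but identical to itself)
  st <- pairwise_identity_similarity("AXC", "AXC", prealigned = TRUE)
  expect_equal(st$identity, 100)
})

test_that("identity and similarity are symmetric in the two sequences", {
  a <- "MGTQWERLLNDAK"
  b <- "MGSQWDRLLQEK"
  ab <- pairwise_identity_similarity(a, b)
  ba <- pairwise_identity_similarity(b, a)
  expect_equal(ab$identity, ba$identity)
  expect_equal(ab$similarity, ba$similarity)
  expect_equal(ab$score, ba$score)
})

test_that("dynamic program attains the exhaustive optimum on short pairs", {
  set.seed(33)
  aas <- c("A", "R", "N", "D", "C", "W", "K", "E", "G")
  for (i in 1:25) {
    a <- paste(sample(aas, sample(1:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:5, 1), replace = TRUE), collapse = "")
    got <- align_global(a, b, gap_open = 10, gap_extend = 0.5)
    want <- oracle_best_alignment_score(a, b, blosum62, 10, 0.5)
    expect_equal(got$score, want,
                 label = sprintf("score(%s, %s)", a, b))
    # the emitted alignment scores exactly what the DP reports
    expect_equal(oracle_score_alignment(strsplit(got$aligned_a, "")[[1]],
                                        strsplit(got$aligned_b, "")[[1]],
                                        blosum62, 10, 0.5),
                 got$score)
  }
})

test_that("alignment scores agree with an independent reference aligner", {
  library(Biostrings)
  data(BLOSUM62, envir = environment())
  set.seed(44)
  aas <- setdiff(rownames(BLOSUM62), c("B", "J", "Z", "X", "*"))
  for (i in 1:10) {
    a <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    # Biostrings charges open + L*ext for a length-L gap; ours charges
    # open + (L-1)*ext, so shift the opening penalty by one extension
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 9.5,
                                         gapExtension = 0.5,
                                         scoreOnly = TRUE)
    got <- align_global(a, b, gap_open = 10, gap_extend = 0.5)
    expect_equal(got$score, ref, label = sprintf("score(%s, %s)", a, b))
  }
})
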