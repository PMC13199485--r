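test_that("roundness of rasterized discs and ellipses matches theory", {
  disc <- cetime:::rasterize_ellipse(100, 100)
  expect_equal(roundness_from_mask(disc), 1, tolerance = 0.02)
  # 2:1 ellipse: 4(pi a b) / (pi (2a)^2) = b/a = 0.5
  ell <- cetime:::rasterize_ellipse(100, 50)
  expect_equal(roundness_from_mask(ell), 0.5, tolerance = 0.02)
  # 4:1
  ell4 <- cetime:::rasterize_ellipse(120, 30)
  expect_equal(roundness_from_mask(ell4), 0.25, tolerance = 0.02)
})

test_that("roundness is invariant to rotation and scale", {
  base <- roundness_from_mask(cetime:::rasterize_ellipse(80, 40))
  for (ang in c(pi / 7, pi / 4, 1.2))
    expect_equal(roundness_from_mask(cetime:::rasterize_ellipse(80, 40,
                                                                ang)),
                 base, tolerance = 0.02)
  expect_equal(roundness_from_mask(cetime:::rasterize_ellipse(160, 80)),
               base, tolerance = 0.02)
})

test_that("degenerate and invalid masks are rejected", {
  m <- matrix(0L, 20, 20)
  expect_error(roundness_from_mask(m), "no labeled region")
  m[5, 5] <- 1L
  expect_error(roundness_from_mask(m), "below minimum")
  # 1-pixel-wide line: roundness near 0
  line <- matrix(0L, 80, 80)
  line[40, 10:70] <- 1L
  expect_lt(roundness_from_mask(line), 0.05)
  # multiple labels need an explicit id
  two <- matrix(0L, 30, 30)
  two[2:12, 2:12] <- 1L
  two[20:29, 20:29] <- 2L
  expect_error(roundness_from_mask(two), "multiple labels")
  expect_silent(roundness_from_mask(two, label = 2, min_area = 50))
})

test_that("polygon roundness agrees with the analytic ellipse value", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- cbind(100 * cos(th), 50 * sin(th))
  expect_equal(roundness_from_polygon(ell), 0.5, tolerance = 1e-3)
  circ <- cbind(60 * cos(th), 60 * sin(th))
  expect_equal(roundness_from_polygon(circ), 1, tolerance = 1e-3)
  expect_error(roundness_from_polygon(cbind(0:1, 0:1)), "vertices")
})

test_that("explant inclusion follows the roundness-by-deadline rule", {
  t <- seq(6, 12.5, by = 0.25)
  dip <- shape_series("e1", "g", t, pmax(0.45, 1 - 0.1 * (t - 6)))
  expect_true(include_explant(dip)$include)   # min 0.45 reached by 12 hpf
  high <- shape_series("e2", "g", t, pmax(0.60, 1 - 0.04 * (t - 6)))
  expect_false(include_explant(high)$include)
  flat <- shape_series("e3", "g", t, rep(1, length(t)))
  expect_false(include_explant(flat)$include)
  short <- shape_series("e4", "g", t[t < 10], rep(0.4, sum(t < 10)))
  expect_warning(dec <- include_explant(short), "indeterminate")
  expect_true(is.na(dec$include))
})

test_that("lowering the roundness cutoff never converts exclude to include", {
  set.seed(42)
  t <- seq(6, 12, by = 0.25)
  for (i in 1:20) {
    r <- pmin(pmax(boltzmann(t, runif(1, 0.1, 0.6), runif(1, 0.7, 1),
                             runif(1, 7, 11), runif(1, 0.2, 1)) +
                     rnorm(length(t), 0, 0.05), 1e-3), 1)
    ser <- shape_series("e", "g", t, r)
    dec_hi <- include_explant(ser, cutoff_roundness = 0.6)$include
    dec_lo <- include_explant(ser, cutoff_roundness = 0.4)$include
    expect_false(dec_lo && !dec_hi)
  }
})

test_that("Boltzmann fit recovers noiseless parameters and the midpoint identity", {
  truth <- c(bottom = 0.25, top = 0.9, v50 = 8.5, slope = 0.7)
  ser <- make_sigmoid_series(truth[1], truth[2], truth[3], truth[4])
  fit <- fit_boltzmann(ser)
  expect_lt(max(abs(fit$coefficients - truth) / truth), 1e-6)
  expect_equal(fit$df, nrow(ser) - 4)
  co <- fit$coefficients
  expect_equal(predict(fit, co["v50"]),
               unname((co["top"] + co["bottom"]) / 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("flat or tiny series are refused with informative errors", {
  t <- seq(6, 12, by = 0.25)
  expect_error(fit_boltzmann(data.frame(hpf = t,
                                        roundness = rep(0.9, length(t)))),
               "flat series")
  expect_error(fit_boltzmann(make_sigmoid_series(t = seq(6, 7, by = 0.25))[1:4, ]),
               "points")
})

test_that("pooled fits across explants recover shared parameters", {
  ser <- gen_shape_series(sim_shape_spec(n_explants = 5, noise_sd = 0.02,
                                         seed = 9))
  fit <- fit_boltzmann(ser)
  expect_equal(unname(fit$coefficients["v50"]), 9, tolerance = 0.1)
  expect_equal(fit$n, sum(vapply(ser, nrow, 0L)))
})

test_that("identical groups give F = 0 and p = 1", {
  g <- make_sigmoid_series(noise_sd = 0.02, seed = 101)
  ft <- compare_fits_f_test(list(a = g, b = g))
  expect_equal(ft$F, 0, tolerance = 1e-6)
  expect_equal(ft$p_value, 1, tolerance = 1e-6)
  expect_true(ft$sse_separate <= ft$sse_pooled + 1e-12)
})

test_that("a planted V50 shift is detected with overwhelming evidence", {
  g1 <- make_sigmoid_series(v50 = 9)
  g2 <- make_sigmoid_series(v50 = 10)
  ft <- compare_fits_f_test(list(a = g1, b = g2))
  expect_lt(ft$p_value, 1e-6)
  expect_equal(ft$df1, 4)
  expect_equal(ft$df2, 2 * nrow(g1) - 8)
  # sharing only V50 also detects the shift
  ft2 <- compare_fits_f_test(list(a = g1, b = g2), share = "v50")
  expect_lt(ft2$p_value, 1e-6)
  expect_equal(ft2$df1, 1)
})

test_that("F-test bookkeeping stays coherent on noisy groups", {
  set.seed(55)
  for (i in 1:5) {
    g1 <- make_sigmoid_series(noise_sd = 0.03)
    g2 <- make_sigmoid_series(noise_sd = 0.03)
    ft <- compare_fits_f_test(list(a = g1, b = g2))
    expect_gte(ft$F, 0)
    expect_true(ft$p_value >= 0 && ft$p_value <= 1)
    expect_lte(ft$sse_separate, ft$sse_pooled + 1e-12)
  }
  expect_error(compare_fits_f_test(list(a = make_sigmoid_series())),
               ">= 2 groups")
  flat <- data.frame(hpf = seq(6, 12, 0.25), roundness = 0.9)
  expect_error(compare_fits_f_test(list(a = make_sigmoid_series(),
                                        bad = flat)), "bad")
})

test_that("extension onset matches the analytic sigmoid crossing", {
  truth <- c(bottom = 0.3, top = 0.95, v50 = 9, slope = 0.5)
  ser <- make_sigmoid_series(truth[1], truth[2], truth[3], truth[4])
  on <- extension_onset_from_series(shape_series("e", "g", ser$hpf,
                                                 ser$roundness))
  # analytic first time the curve is 5% below Top
  t_star <- truth["v50"] + truth["slope"] *
    log((truth["top"] - truth["bottom"]) /
          (0.95 * truth["top"] - truth["bottom"]) - 1)
  expect_lt(abs(on - t_star), 2 / 6 + 1e-9)  # within 2 frames (10 min each)
})

test_that("step and constant series give exact / absent onsets", {
  t <- seq(6, 12, by = 0.1)
  r <- c(rep(1, 29), rep(0.5, length(t) - 29))
  on <- extension_onset_from_series(shape_series("e", "g", t, r))
  expect_equal(on, t[30])
  none <- extension_onset_from_series(shape_series("e", "g", t,
                                                   rep(0.9, length(t))))
  expect_true(is.na(none))
  expect_error(extension_onset_from_series(shape_series("e", "g", t[1:3],
                                                        rep(1, 3))),
               "plateau")
})

test_that("length/width ratio handles straight and curved midlines", {
  straight <- length_width_ratio(cbind(c(0, 4), c(0, 0)),
                                 cbind(c(0, 0), c(0, 2)))
  expect_equal(straight$ratio, 2)
  bent <- length_width_ratio(cbind(c(0, 1, 2), c(0, 1, 0)),
                             cbind(c(0, 0), c(0, 1)))
  expect_equal(bent$ratio, 2 * sqrt(2), tolerance = 1e-12)
  expect_error(length_width_ratio(cbind(1, 1), cbind(c(0, 0), c(0, 1))),
               ">= 2 points")
  expect_error(length_width_ratio(cbind(c(0, 4), c(0, 0)),
                                  rbind(c(1, 1), c(1, 1))),
               "zero length")
})
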