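test_that("Pearson correlations match the textbook formulas to 1e-12", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.9, 6.0, 3.3)
  y <- c(2.0, 3.1, 2.5, 4.9, 5.2, 2.7, 5.8, 3.0)
  n <- length(x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- atanh(r_hand)
  ci_hand <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  t_stat <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_stat), df = n - 2)
  rep <- peak_correlations(tibble::tibble(a = x, b = y), list(c("a", "b")))
  expect_equal(rep$r, r_hand, tolerance = 1e-12)
  expect_equal(rep$conf_low, ci_hand[1], tolerance = 1e-12)
  expect_equal(rep$conf_high, ci_hand[2], tolerance = 1e-12)
  expect_equal(rep$p_value, p_hand, tolerance = 1e-12)
  expect_equal(rep$n, n)
})

test_that("identical vectors correlate perfectly; independent ones do not", {
  set.seed(27)
  x <- rnorm(50)
  rep1 <- peak_correlations(tibble::tibble(a = x, b = x), list(c("a", "b")))
  expect_equal(rep1$r, 1, tolerance = 1e-12)
  # null coverage: for independent Gaussians at n = 1000, |r| < 0.08
  # (about 2.5 sd) should hold in at least ~95% of replicates
  set.seed(25)
  r_null <- replicate(40, {
    peak_correlations(tibble::tibble(a = rnorm(1000), b = rnorm(1000)),
                      list(c("a", "b")))$r
  })
  expect_gte(mean(abs(r_null) < 0.08), 0.9)
  expect_lt(median(abs(r_null)), 0.05)
})

test_that("pairs with fewer than 3 complete cases are reported as not computed", {
  d <- tibble::tibble(a = c(1, 2, NA, NA), b = c(1, NA, 3, NA))
  rep <- peak_correlations(d, list(c("a", "b")))
  expect_true(is.na(rep$r))
  expect_equal(rep$n, 1)
})

test_that("MN-level triphasic detection sees subthreshold-for-muscle patterns", {
  # MN bumps present, muscles silent: triphasic at the MN level only
  tr <- synth_trace(
    amplitude = 40, duration = 0.8,
    bumps = list(FlxAlpha = bump_set(c(5.1, 5.7), c(12, 6), 0.06),
                 ExtAlpha = bump_set(5.4, 9, 0.06)))
  mn <- mn_level_triphasic(tr)
  expect_true(mn$is_triphasic)
  emg <- classify_triphasic(detect_peaks(tr$flex_emg, tr$time),
                            detect_peaks(tr$ext_emg, tr$time))
  expect_false(emg$is_triphasic)
  # flat MN traces are not triphasic
  expect_false(mn_level_triphasic(synth_trace(amplitude = 0))$is_triphasic)
})

test_that("EMG-level triphasic implies MN-level triphasic on driven traces", {
  tr <- synth_trace(
    amplitude = 40, duration = 0.8,
    bumps = list(flex_emg = bump_set(c(5.1, 5.7), c(25, 10), 0.06),
                 ext_emg = bump_set(5.4, 18, 0.06),
                 FlxAlpha = bump_set(c(5.1, 5.7), c(15, 8), 0.06),
                 ExtAlpha = bump_set(5.4, 10, 0.06)))
  m <- evaluate_movement(tr)
  expect_true(m$triphasic)
  expect_true(mn_level_triphasic(tr)$is_triphasic)
})

test_that("movement peak amplitudes extract the mechanism channels", {
  tr <- synth_trace(
    amplitude = 40, duration = 0.8,
    bumps = list(FlxAlpha = bump_set(c(5.1, 5.7), c(15, 8), 0.05),
                 FlxPN = bump_set(c(5.15, 5.72), c(11, 6), 0.05),
                 Ext1b = bump_set(5.45, 20, 0.05),
                 ExtAlpha = bump_set(5.4, 10, 0.05),
                 Flx1a = bump_set(5.65, 7, 0.05)))
  pk <- movement_peak_amplitudes(tr)
  expect_equal(pk$flxalpha_peak1, 15, tolerance = 0.2)
  expect_equal(pk$flxalpha_peak2, 8, tolerance = 0.2)
  expect_equal(pk$flxpn_peak2, 6, tolerance = 0.2)
  expect_equal(pk$ext1b_peak, 20, tolerance = 0.2)
  expect_equal(pk$extalpha_peak, 10, tolerance = 0.2)
  expect_equal(pk$flx1a_late_peak, 7, tolerance = 0.2)
  expect_true(is.na(pk$ext1a_peak))
})

test_that("lesion screening classifies outcomes against the baseline replay", {
  topo <- build_topology("full50")
  v <- find_moving_vector(topo)
  rep <- lesion_screen(v, topo, list(
    none = lesion_spec(),
    all_afferents = lesion_spec(clamped_neurons = c(
      Flx1a = -65, Ext1a = -65, Flx1b = -65, Ext1b = -65))))
  expect_s3_class(rep, "lesion_report")
  expect_equal(rep$outcome[rep$lesion == "none"], "unchanged")
  expect_equal(rep$max_angle_dev[rep$lesion == "none"], 0)
  # the empty lesion is bit-identical to baseline
  expect_identical(as.data.frame(rep$trace[[1]]),
                   as.data.frame(attr(rep, "baseline")))
})
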