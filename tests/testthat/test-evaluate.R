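test_that("minimum-jerk template anchors and peak-speed identity", {
  expect_equal(minjerk_template(40, 0.8, 5, 5), 0)
  expect_equal(minjerk_template(40, 0.8, 5, 5.8), 40)
  expect_equal(minjerk_template(40, 0.8, 5, 10), 40)     # held after end
  expect_equal(minjerk_template(40, 0.8, 5, 0), 0)       # flat before onset
  # numeric peak speed equals 1.875 * A / D at tau = 0.5
  t <- seq(5, 5.8, by = 1e-5)
  v <- diff(minjerk_template(40, 0.8, 5, t)) / 1e-5
  expect_equal(max(v), 1.875 * 40 / 0.8, tolerance = 1e-6)
  expect_equal(t[which.max(v)] - 5, 0.4, tolerance = 1e-3)
})

test_that("fit_minjerk recovers noiseless template parameters across the behavior range", {
  for (A in c(10, 40, 110)) {
    for (D in c(0.3, 1, 2)) {
      tr <- synth_trace(amplitude = A, duration = D, onset = 5.3)
      f <- fit_minjerk(tr)
      expect_lt(abs(f$amplitude - A) / A, 0.01, label = sprintf("A=%g D=%g", A, D))
      expect_lt(abs(f$duration - D) / D, 0.02, label = sprintf("A=%g D=%g", A, D))
      expect_lt(f$mse, 1e-6)
      expect_equal(f$onset_time, 5.3, tolerance = 0.02)
    }
  }
})

test_that("white angle noise appears as its variance in the fit mse", {
  set.seed(11)
  tr <- synth_trace(amplitude = 40, duration = 0.8, noise_sd = 0.5)
  f <- fit_minjerk(tr)
  expect_equal(f$mse, 0.25, tolerance = 0.15)
})

test_that("a flat trace yields zero amplitude and the right rejection flags", {
  tr <- synth_trace(amplitude = 0)
  f <- fit_minjerk(tr)
  expect_equal(f$amplitude, 0)
  m <- evaluate_movement(tr)
  expect_false(m$valid)
  expect_match(m$reasons, "amplitude-range")
})

test_that("co-contraction penalty implements the clamped product form", {
  t <- seq(0, 10, by = 0.01)
  both_on <- rep(-50, length(t))
  at_thr <- rep(-60, length(t))
  below <- rep(-70, length(t))
  # both at -50 mV for the whole window: 100 * (10 * 10) = 10,000
  expect_equal(cocontraction_penalty(both_on, both_on, t, c(2, 5)), 10000)
  expect_equal(cocontraction_penalty(at_thr, at_thr, t, c(2, 5)), 0)
  expect_equal(cocontraction_penalty(both_on, below, t, c(2, 5)), 0)
  expect_equal(cocontraction_penalty(below, both_on, t, c(7, 10)), 0)
})

test_that("cost is near zero for a perfect movement and gates preparatory drift", {
  tr <- synth_trace(amplitude = 40, duration = 0.8)
  f <- fit_minjerk(tr)
  cb <- cost(tr, f)
  expect_lt(cb$total_cost, 1e-8)
  expect_equal(cb$total_cost, cb$tracking_term + cb$penalty_prep +
                 cb$penalty_main)
  # 5 degrees of drift during the preparatory phase alone exceeds the
  # validity threshold
  tr2 <- synth_trace(amplitude = 40, duration = 0.8)
  drift <- tr2$time >= 2.5 & tr2$time < 5
  tr2$angle[drift] <- tr2$angle[drift] + 5
  f2 <- fit_minjerk(tr2)
  expect_gt(cost(tr2, f2)$total_cost, 1)
})

test_that("adding co-contraction never decreases the cost", {
  tr <- synth_trace(amplitude = 40, duration = 0.8)
  f <- fit_minjerk(tr)
  c0 <- cost(tr, f)$total_cost
  tr$FlxAlpha <- tr$FlxAlpha + 8   # both MNs above threshold in all windows
  tr$ExtAlpha <- tr$ExtAlpha + 8
  expect_gt(cost(tr, f)$total_cost, c0)
})

test_that("peak detection matches the exhaustive brute-force scan", {
  expect_equal(nrow(detect_peaks(rep(-60, 100))$peaks), 0)
  set.seed(12)
  for (i in 1:1000) {
    y <- random_pl_signal()
    got <- detect_peaks(y)$peaks
    want <- brute_force_peaks(y)
    expect_equal(got$time, want$time)
    expect_equal(got$value, want$value)
  }
})

test_that("a single bump gives one peak at its apex; plateaus report their center", {
  tr <- synth_trace(bumps = list(flex_emg = bump_set(5.2, 30)))
  pk <- detect_peaks(tr$flex_emg, tr$time)
  expect_equal(nrow(pk$peaks), 1)
  expect_equal(pk$peaks$time, 5.2, tolerance = 1e-9)
  expect_equal(pk$peaks$value, -30, tolerance = 1e-6)
  y <- c(-60, -60, -50, -40, -40, -40, -50, -60)
  pk2 <- detect_peaks(y)
  expect_equal(nrow(pk2$peaks), 1)
  expect_equal(pk2$peaks$time, 5)   # center sample of the plateau
})

test_that("minima are reported between consecutive peaks", {
  y <- c(-60, -40, -55, -30, -60)
  pk <- detect_peaks(y)
  expect_equal(nrow(pk$peaks), 2)
  expect_equal(pk$minima$time, 3)
  expect_equal(pk$minima$value, -55)
})

test_that("triphasic classification follows the betweenness rule", {
  flex2 <- make_peak_set(c(5.1, 5.6), c(-30, -45))
  ext_mid <- make_peak_set(5.35, -40)
  ext_early <- make_peak_set(5.0, -40)
  flex1 <- make_peak_set(5.1, -30)
  lab <- classify_triphasic(flex2, ext_mid)
  expect_true(lab$is_triphasic)
  expect_equal(lab$ag1$time, 5.1)
  expect_equal(lab$ant$time, 5.35)
  expect_equal(lab$ag2$time, 5.6)
  expect_false(classify_triphasic(flex1, ext_mid)$is_triphasic)
  expect_false(classify_triphasic(flex2, ext_early)$is_triphasic)
  expect_false(classify_triphasic(flex2, make_peak_set(numeric(0),
                                                       numeric(0)))$is_triphasic)
})

test_that("triphasic classification is invariant to uniform time shifts", {
  set.seed(13)
  for (i in 1:20) {
    ft <- sort(5 + runif(2))
    et <- 5 + runif(1)
    for (shift in c(-0.5, 0, 1.3)) {
      a <- classify_triphasic(make_peak_set(ft, c(-30, -40)),
                              make_peak_set(et, -35))
      b <- classify_triphasic(make_peak_set(ft + shift, c(-30, -40)),
                              make_peak_set(et + shift, -35))
      expect_equal(a$is_triphasic, b$is_triphasic)
    }
  }
})

test_that("evaluate_movement applies every validity rule", {
  ok <- evaluate_movement(synth_trace(amplitude = 42.88, duration = 0.8))
  expect_true(ok$valid)
  expect_equal(ok$amplitude, 42.88, tolerance = 1e-3)
  too_small <- evaluate_movement(synth_trace(amplitude = 8, duration = 0.8))
  expect_false(too_small$valid)
  expect_match(too_small$reasons, "amplitude-range")
  too_big <- evaluate_movement(synth_trace(amplitude = 115, duration = 0.8))
  expect_match(too_big$reasons, "amplitude-range")
  # 5-95% duration of a 4 s template is about 2.4 s: rejected as too slow
  slow <- evaluate_movement(synth_trace(amplitude = 40, duration = 4))
  expect_false(slow$valid)
  expect_match(slow$reasons, "too-slow")
  # triphasic metadata propagates
  tri <- evaluate_movement(synth_trace(
    amplitude = 42.88, duration = 0.8,
    bumps = list(flex_emg = bump_set(c(5.15, 5.8), c(28, 12), 0.06),
                 ext_emg = bump_set(5.45, 20, 0.06))))
  expect_true(tri$triphasic)
  expect_lt(tri$ag1_time, tri$ant_time)
  expect_lt(tri$ant_time, tri$ag2_time)
  expect_equal(tri$ag1_amp, 28, tolerance = 0.2)
})

test_that("an unstable trial is scored invalid with reason 'unstable'", {
  tr <- synth_trace(amplitude = 40, duration = 0.8)
  attr(tr, "failed") <- TRUE
  m <- evaluate_movement(tr)
  expect_false(m$valid)
  expect_equal(m$reasons, "unstable")
})
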