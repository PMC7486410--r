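test_that("a single synchronous column is detected as exactly one GDP", {
  r <- make_raster(100, 200, cbind(1:100, 51), frame_rate_hz = 10)
  cat_ <- detect_gdps(r, n_surrogates = 200, seed = 1)
  expect_identical(cat_$t_G, 50L)          # 0-based peak frame
  expect_length(cat_$participants[[1]], 100)
  # empty raster gives an empty catalog
  expect_length(detect_gdps(make_raster(5, 50, NULL))$t_G, 0)
})

test_that("suprathreshold-frame fraction on an independent raster matches the percentile rule", {
  # high-rate raster so population sums are fine-grained; under independence
  # the pooled surrogate distribution equals the data's own sum distribution,
  # so the strictly-above fraction sits just under 1%
  r <- poisson_raster(200, 4000, 0.1, seed = 3)
  cat_ <- detect_gdps(r, n_surrogates = 200, seed = 4)
  expect_gt(cat_$frac_suprathreshold, 0.002)
  expect_lt(cat_$frac_suprathreshold, 0.015)
  # oracle: left-continuous 99th percentile of the raster's own sums
  s <- colSums(r$onsets)
  thr_oracle <- sort(s)[ceiling(0.99 * length(s))]
  expect_lte(abs(cat_$threshold - thr_oracle), 1)
})

test_that("detected GDP rate on the calibrated slice generator matches 0.02 Hz", {
  s <- gen_slice_session(slice_sim_spec(seed = 1))
  cat_ <- detect_gdps(s$raster, seed = 2)
  expected <- 0.02 * 900
  expect_gte(length(cat_$t_G), qpois(0.025, expected))
  expect_lte(length(cat_$t_G), qpois(0.975, expected))
})

test_that("reported peaks exceed the threshold and honour the separation", {
  for (sd in 1:4) {
    s <- gen_slice_session(slice_sim_spec(n_cells = 60, duration_s = 300,
                                          seed = sd))
    cat_ <- detect_gdps(s$raster, n_surrogates = 300,
                        min_separation_s = 2, seed = sd)
    sums <- colSums(s$raster$onsets)
    expect_true(all(sums[cat_$t_G + 1L] > cat_$threshold))
    if (length(cat_$t_G) > 1) {
      expect_true(all(diff(cat_$t_G) >= 2 * s$raster$frame_rate_hz))
    }
  }
})

test_that("windowed-IGI frequency test classifies deterministic changes", {
  fr <- 10
  proto <- stimulation_protocol(
    integer(), 50,
    list(pre = c(0L, 6000L), stim = c(6000L, 12000L), post = c(12000L, 18000L)))
  # identical (time-shifted) trains in all epochs -> no effect
  tg <- c(seq(25, 575, 50), seq(625, 1175, 50), seq(1225, 1775, 50))
  none <- test_frequency_effect(make_catalog(tg, fr, 18000L), proto,
                                t_s_frames = 1500)
  expect_identical(none$classification, "none")
  expect_true(all(none$ks_p > 0.5))
  # control IGI 50 s, stimulation IGI 25 s -> increase in frequency;
  # point-mass distributions give KS statistic 1 and a tiny exact p
  tg2 <- c(seq(25, 575, 50), seq(605, 1195, 25), seq(1225, 1775, 50))
  up <- test_frequency_effect(make_catalog(tg2, fr, 18000L), proto,
                              t_s_frames = 1500)
  expect_identical(up$classification, "increase")
  expect_lt(up$ks_p[["pre_stim"]], 0.001)
  # permutation oracle: D = 1 is attained only by the unmixed split
  w_pre <- up$windowed$pre; w_stim <- up$windowed$stim
  expect_true(all(w_pre == 50) && all(w_stim == 25))
  p_perm <- 2 / choose(length(w_pre) + length(w_stim), length(w_pre))
  expect_lt(p_perm, 0.001)
  # reversed: stimulation slows the rhythm
  tg3 <- c(seq(25, 575, 25), seq(605, 1195, 50), seq(1225, 1775, 25))
  expect_identical(
    test_frequency_effect(make_catalog(tg3, fr, 18000L), proto,
                          t_s_frames = 1500)$classification, "decrease")
})

test_that("slices with unstable control rhythm or too few GDPs are excluded", {
  fr <- 10
  proto <- stimulation_protocol(
    integer(), 50,
    list(pre = c(0L, 6000L), stim = c(6000L, 12000L), post = c(12000L, 18000L)))
  # control IGIs 1,1,1,300 s: CV ~ 1.7 > 1 -> excluded
  tg <- c(100, 101, 102, 103, 403, seq(700, 1100, 50), seq(1300, 1700, 50))
  res <- test_frequency_effect(make_catalog(tg, fr, 18000L), proto,
                               t_s_frames = 1500)
  expect_false(res$included)
  expect_identical(res$classification, "excluded")
  expect_gt(res$cv_control, 1)
  # a nearly empty epoch is not assessable
  tg2 <- c(seq(25, 575, 50), 700, seq(1225, 1775, 50))
  res2 <- test_frequency_effect(make_catalog(tg2, fr, 18000L), proto,
                                t_s_frames = 1500)
  expect_identical(res2$classification, "not assessable")
})

test_that("phase series follows the harmonic-oscillator identity", {
  # perfectly periodic train: phase identically zero
  ps <- compute_phase_series(seq(50, 500, 50), delta_t_s = 50)
  expect_true(all(ps$phi == 0))
  expect_true(ps$included)
  # direct substitution: third GDP at 160 s with a 50 s period
  ps2 <- compute_phase_series(c(50, 100, 160), delta_t_s = 50)
  expect_equal(ps2$phi[3], 0.2)
  # control drift beyond +/-2 cycles excludes the recording
  ps3 <- compute_phase_series(c(50, 100, 275), delta_t_s = 50)
  expect_equal(ps3$phi[3], 2.5)
  expect_false(ps3$included)
  expect_error(compute_phase_series(c(1, 2), delta_t_s = 0), "positive")
})

test_that("phase series is translation-covariant", {
  set.seed(5)
  t0 <- cumsum(runif(8, 30, 70))
  for (k in c(1, 2, -1)) {
    a <- compute_phase_series(t0, 50)$phi
    b <- compute_phase_series(t0 + k * 50, 50)$phi
    expect_equal(b, a + k)
  }
})

test_that("constructed stimulation-locked GDPs are detected at the right latency", {
  fr <- 10; tt <- 9000L
  epochs <- list(pre = c(0L, 3000L), stim = c(3000L, 6000L),
                 post = c(6000L, 9000L))
  stim <- seq(3000L, 5900L, 100L)
  m <- matrix(0L, 60, tt)
  for (s in stim) m[1:55, s + 20L + 1L] <- 1L    # GDP 2 s after every stim
  r <- activity_raster(m, fr)
  proto <- stimulation_protocol(stim, 50L, epochs, 0.1, tt)
  cat_ <- detect_gdps(r, n_surrogates = 200, seed = 1)
  lk <- test_gdp_locking(r, proto, cat_, seed = 2)
  expect_true(lk$significant)
  expect_equal(lk$latency_s, 2)
  expect_equal(lk$p, 0)
  # ties between equal peaks report the earliest latency
  m2 <- matrix(0L, 60, tt)
  for (s in stim) {
    m2[1:30, s + 11L] <- 1L
    m2[31:60, s + 21L] <- 1L
  }
  r2 <- activity_raster(m2, fr)
  cat2 <- detect_gdps(r2, n_surrogates = 200, seed = 1)
  lk2 <- test_gdp_locking(r2, proto, cat2, seed = 2)
  expect_equal(lk2$latency_s, 1)
  # no GDP during stimulation -> not assessable
  m3 <- matrix(0L, 60, tt); m3[1:55, 500] <- 1L
  cat3 <- detect_gdps(activity_raster(m3, fr), n_surrogates = 200, seed = 1)
  lk3 <- test_gdp_locking(activity_raster(m3, fr), proto, cat3, seed = 2)
  expect_false(lk3$assessable)
})

test_that("hub-effect generator yields significant locking near 2.2 s", {
  hits <- 0; lat <- numeric()
  for (sd in 1:5) {
    s <- gen_slice_session(slice_sim_spec(
      n_cells = 80, duration_s = 600, seed = sd,
      hub_effect = hub_locking(2.2, 0.3, 0.9)))
    cat_ <- detect_gdps(s$raster, seed = sd)
    lk <- test_gdp_locking(s$raster, s$protocol, cat_, seed = sd)
    hits <- hits + isTRUE(lk$significant)
    lat <- c(lat, lk$latency_s)
  }
  expect_gte(hits, 4)
  expect_lt(abs(median(lat) - 2.2), 0.5)
})
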