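test_that("z-scored PSTH matches a hand-computed oracle", {
  fr <- 10
  m <- matrix(0L, 2, 400)
  events <- c(100L, 200L, 300L)            # 0-based
  # cell 1: spikes at fixed offsets around each event + two baseline spikes
  for (e in events) m[1, e + 1 + c(0, 3)] <- 1L
  m[1, c(85, 185)] <- 1L
  r <- activity_raster(m, fr)
  z <- zpsth(r, 1, events, window_s = 4, baseline_end_s = 0)
  half <- 20
  # brute-force oracle built directly from the definition
  psth_o <- rowMeans(vapply(events, function(e) {
    m[1, (e - half + 1):(e + half + 1)]
  }, numeric(2 * half + 1)))
  bl <- ((seq_len(2 * half + 1) - 1 - half) / fr) < 0
  mu_o <- mean(psth_o[bl]); sd_o <- sd(psth_o[bl])
  expect_equal(z$psth, psth_o)
  expect_equal(z$mu_b, mu_o)
  expect_equal(z$z, (psth_o - mu_o) / sd_o)
  # silent cell: sigma_B = 0, Z undefined and flagged
  z2 <- zpsth(r, 2, events, window_s = 4)
  expect_false(z2$defined)
  expect_true(all(is.na(z2$z)))
})

test_that("cells firing only during locomotion are locomotion-ON via the ratio test", {
  set.seed(21)
  fr <- 10
  mv <- rep(rep(c(0, 1), 12), each = 100)[1:2400]   # 12 bouts of 10 s
  ep <- derive_epochs(mv, fr)
  m <- matrix(rbinom(30 * 2400, 1L, 0.008), 30, 2400)
  loco_cols <- epoch_frames(ep$locomotion) + 1L
  m[1, ] <- 0L
  m[1, sample(loco_cols, 25)] <- 1L                 # cell 1: locomotion only
  r <- activity_raster(m, fr)
  res <- classify_locomotion(r, ep$locomotion, ep$rest, n_shuffles = 500,
                             seed = 3)
  expect_true(res$ratio_sig[1])
  expect_true(res$locomotion_on[1])
})

test_that("locomotion false-positive rate on rate-constant cells stays below 10%", {
  set.seed(31)
  fr <- 9.85
  # 60 bouts so onset counts are in the method's calibrated regime
  mv <- rep(rep(c(0, 1), 60), each = 197)
  ep <- derive_epochs(mv, fr)
  r <- activity_raster(matrix(rbinom(500 * length(mv), 1L, 0.01), 500), fr)
  res <- classify_locomotion(r, ep$locomotion, ep$rest, n_shuffles = 500,
                             seed = 7)
  expect_lt(mean(res$locomotion_on), 0.10)
})

test_that("one silent-background co-activation bin is exactly one SCE", {
  fr <- 10
  m <- matrix(0L, 100, 600)
  m[1:50, 301] <- 1L
  # sprinkle a few isolated, non-coincident spikes so surrogates are defined
  m[cbind(95:100, seq(20, 120, 20))] <- 1L
  r <- activity_raster(m, fr)
  rest <- epoch_set("rest", c(0L, 600L), 600L)
  sce <- detect_sces(r, rest, n_surrogates = 300, seed = 2)
  expect_length(sce$bins, 1)
  expect_equal(sce$peak_frames, 300L)
  expect_length(sce$participants[[1]], 50)
  # empty rest -> empty catalog
  empty <- detect_sces(r, epoch_set("rest", NULL, 600L), seed = 2)
  expect_length(empty$bins, 0)
})

test_that("SCE catalogs are monotone in the threshold percentile", {
  r <- poisson_raster(80, 3000, 0.02, frame_rate_hz = 9.85, seed = 8)
  rest <- epoch_set("rest", c(0L, 3000L), 3000L)
  c99 <- detect_sces(r, rest, pctile = 99, n_surrogates = 300, seed = 5)
  c95 <- detect_sces(r, rest, pctile = 95, n_surrogates = 300, seed = 5)
  expect_gte(c99$threshold, c95$threshold)
  supra99 <- which(c99$bin_sums > c99$threshold)
  supra95 <- which(c95$bin_sums > c95$threshold)
  expect_true(all(supra99 %in% supra95))
})

test_that("detected SCE rate on the calibrated generator lies in the reported band", {
  for (sd in 1:2) {
    ss <- gen_invivo_session(invivo_sim_spec(
      n_cells = 120, duration_s = 600, seed = sd,
      loco_modulated_fraction = 0))
    sce <- detect_sces(ss$raster, ss$epochs$rest, seed = sd + 10)
    expect_gte(sce$rate_hz, 0.04)
    expect_lte(sce$rate_hz, 0.12)
    # every detected SCE bin lies inside a rest epoch
    iv <- ss$epochs$rest$intervals
    ok <- vapply(sce$bin_start_frames, function(f)
      any(f >= iv[, 1] & f < iv[, 2]), logical(1))
    expect_true(all(ok))
  }
})

test_that("SCE-ON classification uses a strict zero-lag threshold", {
  fr <- 10
  m <- matrix(0L, 3, 300)
  e <- 150L
  m[1, e + 1] <- 1L              # cell 1 spikes at the event...
  m[1, e - 10 + 1] <- 1L         # ...and once in the 20-bin baseline
  m[2, e + 1] <- 1L              # cell 2: event only, silent baseline
  r <- activity_raster(m, fr)
  sces <- detect_sces_stub(e, fr, 300L)
  # analytic zero-lag Z for cell 1: baseline = 19 zeros and one 1
  z0 <- (1 - 0.05) / sqrt((0.95^2 + 19 * 0.05^2) / 19)
  res <- classify_sce_on(r, sces, z_thresh = z0)        # equality: not ON
  expect_equal(res$z_zero_lag[1], z0)
  expect_false(res$sce_on[1])
  res2 <- classify_sce_on(r, sces, z_thresh = z0 - 1e-9)
  expect_true(res2$sce_on[1])
  # default threshold of 3 is exceeded
  expect_true(classify_sce_on(r, sces)$sce_on[1])
  # zero baseline SD -> indeterminate
  res3 <- classify_sce_on(r, sces)
  expect_true(is.na(res3$sce_on[2]))
  expect_true(res3$indeterminate[2])
})

test_that("cells independent of SCEs are rarely SCE-ON", {
  set.seed(41)
  fr <- 9.85
  r <- poisson_raster(300, 4000, 0.015, frame_rate_hz = fr, seed = 13)
  events <- sort(sample(200:3800, 25))
  sces <- detect_sces_stub(events, fr, 4000L)
  res <- classify_sce_on(r, sces)
  expect_lt(mean(res$sce_on, na.rm = TRUE), 0.08)
})
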