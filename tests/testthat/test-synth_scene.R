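test_that("chirp synthesis: length, spectrum, sweep range", {
  x <- synth_chirp(70000, 70000, 0.05, 250000)
  expect_length(x, 12500)
  expect_equal(max(abs(x)), 1)
  # pure tone: spectral peak at 70 kHz
  X <- Mod(stats::fft(x))[1:6250]
  f <- (0:6249) * 250000 / 12500
  expect_equal(f[which.max(X)], 70000, tolerance = 100)
  # sweep: instantaneous-frequency ridge stays within the endpoints
  y <- synth_chirp(50000, 80000, 0.06, 250000)
  ridge <- ridge_oracle(y, 250000)
  expect_true(all(ridge >= 49000 & ridge <= 81000))
  expect_lt(ridge[2], ridge[length(ridge) - 1])  # upward sweep
  expect_error(synth_chirp(130000, 140000, 0.01, 250000))
})

test_that("fractional delay shifts by the requested sub-sample amount", {
  fs <- 250000
  # wideband sweep: unambiguous correlation peak (no cycle skipping)
  x <- synth_chirp(45000, 90000, 0.02, fs)
  d <- 17.4 / fs
  y <- frac_delay(x, d, fs, length(x) + 64)
  td <- xcorr_tdoa_oracle(y, c(x, numeric(64)), fs, 40)
  expect_lt(abs(td - 17.4 / fs), 1.01 / fs)
})

test_that("propagation to microphones follows geometry and 1/r law", {
  fs <- 250000
  wav <- synth_chirp(55000, 75000, 0.02, fs)
  mics <- rbind(c(100, 0, 465), c(-100, 0, 465), c(0, 200, 465))
  src <- c(0, 0, 10)
  rec <- propagate_to_mics(wav, src, mics, fs)
  # mics 1 and 2 are equidistant from the source: identical channels
  expect_equal(rec$samples[, 1], rec$samples[, 2], tolerance = 1e-10)
  # doubling distance halves amplitude
  m_near <- c(0, 0, 110)   # r = 100
  m_far <- c(0, 0, 210)    # r = 200
  rec2 <- propagate_to_mics(wav, src, rbind(m_near, m_far), fs)
  rms <- apply(rec2$samples, 2, function(v) sqrt(mean(v^2)))
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.01)
  # inter-channel delay equals geometric TDOA within half a sample
  mics2 <- rbind(c(0, 0, 465), c(120, 80, 465))
  rec3 <- propagate_to_mics(wav, src, mics2, fs)
  td <- xcorr_tdoa_oracle(rec3$samples[, 1], rec3$samples[, 2], fs, 200)
  geo <- propagation_delay(src, mics2[2, ]) - propagation_delay(src, mics2[1, ])
  expect_lt(abs(td + geo), 1 / (2 * fs))
})

test_that("sensor noise models: identity, rising MEMS floor, SNR target", {
  fs <- 250000
  wav <- synth_chirp(50000, 80000, 0.2, fs)
  rec <- propagate_to_mics(wav, c(0, 0, 10),
                           rbind(c(0, 0, 465), c(50, 0, 465)), fs)
  expect_identical(add_sensor_noise(rec, "cam64", Inf), rec)

  set.seed(11)
  nz <- shaped_noise(2^17, 1, fs, "cam64")
  p <- psd_oracle(nz[, 1], fs)
  p50 <- mean(p$psd[p$freqs > 45000 & p$freqs < 55000])
  p90 <- mean(p$psd[p$freqs > 85000 & p$freqs < 95000])
  expect_gt(p90, p50)   # noise floor rises with frequency
  nzf <- shaped_noise(2^17, 1, fs, "usm4")
  pf <- psd_oracle(nzf[, 1], fs)
  f50 <- mean(pf$psd[pf$freqs > 45000 & pf$freqs < 55000])
  f90 <- mean(pf$psd[pf$freqs > 85000 & pf$freqs < 95000])
  expect_equal(f90 / f50, 1, tolerance = 0.15)  # flat within estimator noise

  set.seed(12)
  band <- c(45000, 85000)
  for (target in c(6, 12)) {
    noisy <- add_sensor_noise(rec, "usm4", target, band)
    sig_p <- mean(c(band_power_oracle(rec$samples[, 1], fs, band),
                    band_power_oracle(rec$samples[, 2], fs, band)))
    res <- noisy$samples - rec$samples
    noi_p <- mean(c(band_power_oracle(res[, 1], fs, band),
                    band_power_oracle(res[, 2], fs, band)))
    measured <- 10 * log10(sig_p / noi_p)
    expect_lt(abs(measured - target), 0.5)
  }
})

test_that("track generator: bounds, determinism, contact profile", {
  tr1 <- gen_tracks(2, 30, profile = "close", seed = 5)
  tr2 <- gen_tracks(2, 30, profile = "close", seed = 5)
  expect_identical(tr1, tr2)
  expect_true(all(abs(tr1$snout_x_mm) <= 200))
  expect_true(all(abs(tr1$snout_y_mm) <= 150))
  # snout never coincides with head centre (gaze defined everywhere)
  expect_true(all((tr1$snout_x_mm - tr1$head_x_mm)^2 +
                  (tr1$snout_y_mm - tr1$head_y_mm)^2 > 0))
  # close-contact profile: most frames within 100 mm snout-snout
  m1 <- tr1[tr1$mouse_id == 1, ]; m2 <- tr1[tr1$mouse_id == 2, ]
  d <- sqrt((m1$snout_x_mm - m2$snout_x_mm)^2 +
            (m1$snout_y_mm - m2$snout_y_mm)^2)
  expect_gte(mean(d < 100), 0.70)
  # far profile: mostly separated
  trf <- gen_tracks(2, 30, profile = "far", seed = 6)
  f1 <- trf[trf$mouse_id == 1, ]; f2 <- trf[trf$mouse_id == 2, ]
  df <- sqrt((f1$snout_x_mm - f2$snout_x_mm)^2 +
             (f1$snout_y_mm - f2$snout_y_mm)^2)
  expect_gte(mean(df > 100), 0.60)
})

test_that("rendered scene: conservation, clicks, clock recovery", {
  b <- get_tiny_bundle()
  expect_equal(nrow(b$ground_truth), nrow(b$schedule))
  expect_true(all(b$ground_truth$offset > b$ground_truth$onset))
  expect_equal(sum(vapply(b$cam64, function(x) x$kind == "click", TRUE)), 2)

  # click-detection oracle recovers the configured clock offset and drift
  clicks_u <- detect_clicks(b$usm4)
  cb <- Filter(function(x) identical(x$kind, "click"), b$cam64)
  clicks_c <- sort(vapply(cb, block_click_time, numeric(1)))
  cm <- align_clocks(clicks_u, clicks_c)
  expect_lt(abs(cm$offset - b$clock["offset"]), 1e-3)
  expect_lt(abs(cm$drift - b$clock["drift"]), 1e-4)

  # zero-USV scene still renders a valid bundle
  tr <- gen_tracks(1, 2, seed = 1)
  b0 <- render_scene(tr, gen_usv_schedule(0, 2), band_snr_db = Inf)
  expect_equal(nrow(b0$ground_truth), 0)
  expect_equal(sum(vapply(b0$cam64, function(x) x$kind == "click", TRUE)), 2)
})

test_that("forward/inverse consistency: rendering then beamforming recovers the source", {
  scene <- default_scene()
  tr <- gen_tracks(1, 3, seed = 9)
  sch <- gen_usv_schedule(1, 3, emitters = 1, seed = 9)
  b <- render_scene(tr, sch, scene, band_snr_db = Inf)
  blk <- b$cam64[[1]]
  est <- localize_cam64(blk$samples,
                        c(sch$f_start - 5000, sch$f_end + 5000), scene)
  truth <- c(b$ground_truth$source_x[1], b$ground_truth$source_y[1])
  expect_lt(sqrt(sum((est$origin - truth)^2)), 2)  # 1 mm grid + <1 mm bias
})
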