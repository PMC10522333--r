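test_that("DSO degenerate cases: single mic, common time shift", {
  fs <- 250000
  x <- synth_chirp(55000, 75000, 0.02, fs)
  sp <- segment_spectra(cbind(x), fs, c(50000, 80000), 16)
  nodes <- as.matrix(expand.grid(x = seq(-50, 50, 25),
                                 y = seq(-50, 50, 25)))
  mic <- rbind(c(0, 0, 465))
  v1 <- compute_dso(sp, nodes, mic, 10)
  # one microphone: steering phases have unit modulus -> constant field
  expect_lt(diff(range(v1)) / max(v1), 1e-9)

  # a common delay on all channels multiplies each frequency term by a
  # unit-modulus factor: DSO unchanged
  mics <- default_scene()$arrays$cam64$mic_positions[1:8, ]
  rec <- propagate_to_mics(x, c(10, 20, 10), mics, fs)
  sp0 <- segment_spectra(rec$samples, fs, c(50000, 80000), 16)
  shifted <- apply(rec$samples, 2, frac_delay, delay_s = 40 / fs, fs = fs,
                   n_out = nrow(rec$samples))
  sp1 <- segment_spectra(shifted, fs, c(50000, 80000), 16)
  d0 <- compute_dso(sp0, nodes, mics, 10)
  d1 <- compute_dso(sp1, nodes, mics, 10)
  expect_equal(d1 / sum(d1), d0 / sum(d0), tolerance = 1e-3)
  expect_true(all(d0 >= 0))
  expect_error(compute_dso(list(S = matrix(0i, 0, 2), freqs = numeric()),
                           nodes, mics, 10))
})

test_that("frequency-domain DSO argmax matches the time-domain oracle", {
  # acceptance: >= 50 random small instances, <= 8 mics, <= 100 nodes
  fs <- 250000
  scene <- default_scene()
  set.seed(101)
  agree <- 0L
  n_inst <- 50L
  for (k in seq_len(n_inst)) {
    nm <- sample(4:8, 1)
    mics <- cbind(runif(nm, -120, 120), runif(nm, -120, 120),
                  runif(nm, 400, 500))
    gx <- seq(-90, 90, by = 20); gy <- seq(-90, 90, by = 20)
    nodes <- as.matrix(expand.grid(x = gx, y = gy))   # 100 nodes
    src_node <- nodes[sample(nrow(nodes), 1), ]
    wav <- synth_chirp(runif(1, 45000, 60000), runif(1, 65000, 85000),
                       0.008, fs)
    rec <- propagate_to_mics(wav, c(src_node, 10), mics, fs)
    sp <- segment_spectra(rec$samples, fs, c(40000, 90000), 24)
    v_fd <- compute_dso(sp, nodes, mics, 10)
    v_td <- td_delay_sum_oracle(rec$samples, fs, mics, nodes, 10,
                                SPEED_OF_SOUND)
    agree <- agree + (which.max(v_fd) == which.max(v_td))
  }
  expect_equal(agree, n_inst)
})

test_that("field SNR follows max/std with its degenerate cases", {
  v <- numeric(2000); v[77] <- 3
  # one hot cell among N: max/sd = sqrt(N) (sample sd)
  expect_equal(snr_cam64(v), 3 / sd(v))
  expect_equal(snr_cam64(v), sqrt(2000), tolerance = 1e-9)
  expect_equal(snr_cam64(5 * v), snr_cam64(v))   # scale invariance
  expect_warning(s <- snr_cam64(rep(1, 100)))
  expect_true(is.infinite(s))
  expect_error(snr_cam64(3))
})

test_that("coarse/fine grids use inclusive node-centred conventions", {
  scene <- default_scene()
  fs <- scene$sample_rate
  x <- synth_chirp(55000, 75000, 0.02, fs)
  rec <- propagate_to_mics(x, c(0, 0, 10),
                           scene$arrays$cam64$mic_positions, fs)
  co <- coarse_scan(rec$samples, c(50000, 80000), scene)
  expect_equal(dim(co$values), c(51, 41))
  fi <- fine_scan(rec$samples, c(50000, 80000), c(0, 0), scene)
  expect_equal(dim(fi$values), c(31, 31))
  # window clipped at the surface boundary
  fi2 <- fine_scan(rec$samples, c(50000, 80000), c(-250, -200), scene)
  expect_equal(dim(fi2$values), c(16, 16))
  # symmetric peak at the window centre: centroid stays at the centre
  expect_equal(unname(fi$centroid), c(0, 0), tolerance = 0.2)
})

test_that("noise-free localization: accuracy, equivariance, consistency", {
  scene <- default_scene()
  fs <- scene$sample_rate
  wav <- synth_chirp(55000, 70000, 0.04, fs)
  mics <- scene$arrays$cam64$mic_positions
  err <- function(src) {
    rec <- propagate_to_mics(wav, c(src, 10), mics, fs)
    est <- localize_cam64(rec$samples, c(50000, 75000), scene)
    sqrt(sum((est$origin - src)^2))
  }
  expect_lt(err(c(0, 0)), 1.5)
  expect_lt(err(c(111.4, -63.2)), 1.5)
  # source outside the platform but inside the margin is still localized
  expect_lt(err(c(215, 30)), 1.5)

  # translation equivariance of the coarse argmax (on-grid shift)
  rec1 <- propagate_to_mics(wav, c(10, 20, 10), mics, fs)
  rec2 <- propagate_to_mics(wav, c(60, -30, 10), mics, fs)
  co1 <- coarse_scan(rec1$samples, c(50000, 75000), scene)
  co2 <- coarse_scan(rec2$samples, c(50000, 75000), scene)
  expect_equal(unname(co2$peak - co1$peak), c(50, -50))

  # split-half consistency: both halves localize to the same origin
  rec <- propagate_to_mics(wav, c(35, 25, 10), mics, fs)
  n <- nrow(rec$samples)
  e1 <- localize_cam64(rec$samples[1:floor(n / 2), ], c(50000, 75000),
                       scene)
  e2 <- localize_cam64(rec$samples[(floor(n / 2) + 1):n, ],
                       c(50000, 75000), scene)
  expect_lt(sqrt(sum((e1$origin - e2$origin)^2)), 1)
})

test_that("very-high-frequency calls lose SNR under the MEMS noise floor", {
  scene <- default_scene()
  fs <- scene$sample_rate
  mics <- scene$arrays$cam64$mic_positions
  set.seed(7)
  snr_of <- function(f1, f2, band) {
    wav <- synth_chirp(f1, f2, 0.04, fs)
    rec <- propagate_to_mics(wav, c(0, 0, 10), mics, fs)
    rec <- add_sensor_noise(rec, "cam64", band = c(30000, 110000),
                            noise_power = 0.02)
    coarse_scan(rec$samples, band, scene)$snr
  }
  snr_mid <- snr_of(55000, 65000, c(50000, 70000))
  snr_vhf <- snr_of(95000, 105000, c(90000, 95000))
  expect_gt(snr_mid, snr_vhf)
})
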