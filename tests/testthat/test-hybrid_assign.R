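test_that("mouth point sits on the snout-to-head line", {
  expect_equal(mouth_point(c(0, 0), c(10, 0), 0), c(0, 0))
  expect_equal(mouth_point(c(0, 0), c(10, 0), 0.02), c(0.2, 0))
  expect_equal(mouth_point(c(0, 0), c(10, 0), -0.15), c(-1.5, 0))
  m <- mouth_point(rbind(c(0, 0), c(5, 5)), rbind(c(10, 0), c(5, 15)), 0.1)
  expect_equal(dim(m), c(2, 2))
  expect_error(mouth_point(c(1, 1), c(1, 1), 0.02))
  expect_error(mouth_point(c(0, 0), c(10, 0), 1.5))
})

test_that("MPI: normalization, symmetry, worked Gaussian example, gate", {
  # single mouse in range
  expect_equal(mpi(c(0, 0), rbind(c(10, 0)), 5)$mpi, 1)
  # two equidistant mice
  m2 <- mpi(c(0, 0), rbind(c(10, 0), c(-10, 0)), 5)
  expect_equal(m2$mpi, c(0.5, 0.5))
  # direct Gaussian evaluation: A at 5 mm, B at 30 mm, sigma 4.8 mm
  m3 <- mpi(c(0, 0), rbind(A = c(5, 0), B = c(30, 0)), 4.8)
  pa <- exp(-25 / (2 * 4.8^2)); pb <- exp(-900 / (2 * 4.8^2))
  expect_equal(unname(m3$mpi[1]), pa / (pa + pb), tolerance = 1e-12)
  expect_gt(m3$mpi[1], 1 - 1e-8)
  expect_equal(sum(m3$mpi), 1)
  # mice beyond the 50 mm gate have P set to zero
  m4 <- mpi(c(0, 0), rbind(c(60, 0), c(0, 80)), 10)
  expect_false(m4$in_range)
  expect_equal(m4$mpi, c(0, 0))
  expect_error(mpi(c(0, 0), rbind(c(1, 1)), -1))
})

test_that("MPI normalization and monotonicity over random configurations", {
  set.seed(303)
  for (i in 1:50) {
    nm <- sample(2:3, 1)
    mouths <- cbind(runif(nm, -40, 40), runif(nm, -40, 40))
    s <- runif(1, 1, 15)
    m <- mpi(c(0, 0), mouths, s)
    if (m$in_range) expect_equal(sum(m$mpi), 1, tolerance = 1e-12)
    # moving mouse 1 closer (others fixed) never lowers its MPI
    closer <- mouths
    closer[1, ] <- closer[1, ] * 0.5
    m2 <- mpi(c(0, 0), closer, s)
    if (m$in_range && m2$in_range)
      expect_gte(m2$mpi[1] + 1e-12, m$mpi[1])
  }
})

test_that("uncertainty calibration scale", {
  expect_equal(calibrate_sigma(rep(0.02, 5), rep(4.0, 7)), 200)
  expect_equal(calibrate_sigma(c(2, 4), c(3, 3)), 1)
  s1 <- calibrate_sigma(c(0.1, 0.3), c(5, 7))
  s2 <- calibrate_sigma(3 * c(0.1, 0.3), c(5, 7))
  expect_equal(s2, s1 / 3)
  expect_error(calibrate_sigma(numeric(), c(1)))
  expect_error(calibrate_sigma(c(0, 0), c(1)))
})

test_that("hybrid selection applies the reliability and residual rules", {
  est <- function(origin, method, snr = 10)
    structure(list(ok = TRUE, origin = origin, uncertainty = 1,
                   snr = snr, method = method),
              class = "localization_estimate")
  mouths <- rbind(`1` = c(0, 0), `2` = c(40, 0))
  # both reliable: smaller residual to its own top mouse wins
  sel <- hybrid_select(est(c(4, 0), "cam64"), est(c(12, 0), "slim"),
                       mouths, 5, 5)
  expect_equal(sel$method, "cam64")
  expect_equal(sel$mouse, "1")
  expect_equal(sel$residual, 4)
  # only one reliable
  sel2 <- hybrid_select(est(c(20, 0), "cam64"), est(c(3, 0), "slim"),
                        mouths, 8, 5)
  expect_equal(sel2$method, "slim")
  # neither exceeds 0.95: unassigned with low-MPI reason
  sel3 <- hybrid_select(est(c(20, 0), "cam64"), est(c(20, 0), "slim"),
                        mouths, 15, 15)
  expect_equal(sel3$method, "none")
  expect_equal(sel3$reason, "low-MPI")
  # estimates far from every mouse: distance gate
  sel4 <- hybrid_select(est(c(200, 150), "cam64"), NULL, mouths, 5, 5)
  expect_equal(sel4$reason, "distance-gate")
  # no estimates at all
  sel5 <- hybrid_select(NULL, NULL, mouths, 5, 5)
  expect_equal(sel5$reason, "no-estimate")
  # SNR-gate variant: picks the array when its field SNR > 5
  sel6 <- hybrid_select(est(c(12, 0), "cam64", snr = 9),
                        est(c(4, 0), "slim"), mouths, 5, 5,
                        snr_rule = TRUE)
  expect_equal(sel6$method, "cam64")
})

test_that("systematic offset recovery and re-centering", {
  set.seed(17)
  mouth <- cbind(runif(40, -100, 100), runif(40, -100, 100))
  est_unbiased <- mouth + matrix(rnorm(80, sd = 0.5), 40)
  off0 <- estimate_systematic_offset(est_unbiased, mouth)
  expect_lt(max(abs(off0)), 0.5)
  est_biased <- est_unbiased + matrix(rep(c(2, 0), each = 40), 40)
  off <- estimate_systematic_offset(est_biased, mouth)
  expect_equal(unname(off), c(2, 0), tolerance = 0.5)
  corrected <- sweep(est_biased, 2, off)
  expect_equal(unname(colMeans(corrected - mouth)), c(0, 0),
               tolerance = 1e-9)
  expect_null(estimate_systematic_offset(est_biased[1:5, ], mouth[1:5, ]))
})

test_that("dataset assignment: distance gate empties far-away tracks", {
  b <- get_tiny_bundle()
  segments <- data.frame(onset_s = c(1, 2), offset_s = c(1.05, 2.05))
  est <- list(
    structure(list(ok = TRUE, origin = c(0, 0), uncertainty = 0.1,
                   snr = 10, method = "cam64"),
              class = "localization_estimate"),
    structure(list(ok = TRUE, origin = c(10, 10), uncertainty = 0.1,
                   snr = 10, method = "cam64"),
              class = "localization_estimate"))
  # park both mice far outside the gate
  tracks <- data.frame(frame = 0:1, time_s = c(0, 3), mouse_id = 1,
                       sex = "M", snout_x_mm = 180, snout_y_mm = 140,
                       head_x_mm = 160, head_y_mm = 140)
  out <- assign_dataset(segments, est, NULL, tracks, scale_cam = 10)
  expect_true(all(out$reason == "distance-gate"))
  expect_true(all(is.na(out$mouse_id)))
})
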