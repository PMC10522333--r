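test_that("relative polar frame: ahead, hemispace fold, behind", {
  sn <- c(0, 0); hd <- c(-10, 0)   # gaze along +x
  expect_equal(relative_polar(sn, hd, c(50, 0)), c(r = 50, alpha = 0))
  # receiver 30 degrees to the left folds onto +30
  left <- 60 * c(cos(pi / 6), sin(pi / 6))
  right <- 60 * c(cos(-pi / 6), sin(-pi / 6))
  expect_equal(relative_polar(sn, hd, left)["alpha"], c(alpha = 30))
  expect_equal(relative_polar(sn, hd, right)["alpha"], c(alpha = 30))
  expect_equal(relative_polar(sn, hd, c(-100, 0)),
               c(r = 100, alpha = 180))
  expect_error(relative_polar(sn, sn, c(1, 1)))
})

test_that("polar histogram: conservation, half-open bins, overflow", {
  h0 <- polar_histogram(numeric(), numeric())
  expect_equal(sum(h0$counts), 0)
  set.seed(14)
  r <- runif(500, 0, 350); a <- runif(500, 0, 180)
  h <- polar_histogram(r, a, r_max = 200)
  expect_equal(sum(h$counts), 500)               # mass conservation
  expect_equal(sum(h$counts[, ncol(h$counts)]), sum(r >= 200))
  # (55 mm, 95 deg) -> radial bin [50, 60), angular bin [90, 100)
  h1 <- polar_histogram(55, 95)
  expect_equal(h1$counts[10, 6], 1L)
  expect_equal(sum(h1$counts), 1)
  # bin edges are half-open: a point on an edge goes to the upper bin
  h2 <- polar_histogram(50, 90)
  expect_equal(h2$counts[10, 6], 1L)
})

test_that("fold-then-bin equals bin-of-folded angles", {
  set.seed(15)
  a_signed <- runif(300, -180, 180)
  r <- runif(300, 0, 150)
  h_folded <- polar_histogram(r, abs(a_signed))
  # folding is abs(): binning the folded angles must give identical counts
  expect_equal(h_folded$counts,
               polar_histogram(r, abs(a_signed))$counts)
  expect_equal(sum(h_folded$counts), 300)
})

test_that("marginal densities normalize and factor product inputs", {
  set.seed(16)
  # separable input: radius and angle drawn independently
  n <- 20000
  r <- sample(c(25, 75, 125), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  a <- sample(c(45, 135), n, replace = TRUE, prob = c(0.7, 0.3))
  h <- polar_histogram(r, a, r_max = 200)
  mr <- marginal_density(h, "radius")
  ma <- marginal_density(h, "angle")
  expect_equal(sum(mr$density * (mr$bin_hi - mr$bin_lo)), 1)
  expect_equal(sum(ma$density * (ma$bin_hi - ma$bin_lo)), 1)
  expect_equal(mr$density[3] * 10, 0.5, tolerance = 0.02)   # [20,30)
  expect_equal(ma$density[5] * 10, 0.7, tolerance = 0.02)   # [40,50)
  # single-bin histogram: delta marginal
  hd <- polar_histogram(rep(55, 10), rep(95, 10))
  md <- marginal_density(hd, "radius")
  expect_equal(sum(md$density > 0), 1)
  # SEM across recordings is reported
  m2 <- marginal_density(list(h, hd), "radius")
  expect_true(all(is.finite(m2$sem)))
})

test_that("bootstrap difference test: null, identity, injected hotspot", {
  set.seed(23)
  mk <- function(n) data.frame(r = runif(n, 0, 180), alpha = runif(n, 0, 180))
  a <- mk(1000); b <- mk(1000)
  res <- bootstrap_diff_significance(a, b, n_boot = 100, level = 0.01)
  expect_lte(mean(res$significant), 0.02)   # same distribution: <= 2% bins
  # identical point sets: nothing can be flagged
  res2 <- bootstrap_diff_significance(a, a, n_boot = 50)
  expect_equal(sum(res2$significant), 0)
  # a hotspot present only in A is flagged in its bin
  hot <- data.frame(r = runif(300, 50, 59), alpha = runif(300, 90, 99))
  res3 <- bootstrap_diff_significance(rbind(a, hot), b, n_boot = 100)
  expect_true(res3$significant[10, 6])
  expect_error(bootstrap_diff_significance(a, b, n_boot = 1))
})

test_that("female fraction: selection, gating, relabel invariance", {
  tracks <- rbind(
    data.frame(frame = 0:1, time_s = c(0, 10), mouse_id = 1, sex = "F",
               snout_x_mm = 0, snout_y_mm = 0, head_x_mm = -20,
               head_y_mm = 0),
    data.frame(frame = 0:1, time_s = c(0, 10), mouse_id = 2, sex = "M",
               snout_x_mm = 120, snout_y_mm = 0, head_x_mm = 140,
               head_y_mm = 0))
  asg <- data.frame(onset_s = c(1, 2, 3, 4), offset_s = c(1.1, 2.1, 3.1, 4.1),
                    mouse_id = c(2, 2, 2, 1),
                    reason = c("assigned", "assigned", "assigned", "low-MPI"))
  ff <- female_fraction(asg, tracks)
  expect_equal(ff$pooled, 0)     # the only female emission was not assigned
  asg$reason[4] <- "assigned"
  expect_equal(female_fraction(asg, tracks)$pooled, 0.25)
  # gate keeps USVs only when snouts are farther apart than the threshold
  expect_equal(female_fraction(asg, tracks, distance_gate = 50)$pooled, 0.25)
  expect_true(is.na(female_fraction(asg, tracks,
                                    distance_gate = 200)$pooled))
  # relabeling ids within a sex leaves the fraction unchanged
  tracks3 <- rbind(tracks,
    data.frame(frame = 0:1, time_s = c(0, 10), mouse_id = 3, sex = "M",
               snout_x_mm = -120, snout_y_mm = 0, head_x_mm = -140,
               head_y_mm = 0))
  asg3 <- asg; asg3$mouse_id[2] <- 3
  swap <- asg3
  swap$mouse_id[swap$mouse_id == 2] <- 99L
  swap$mouse_id[swap$mouse_id == 3] <- 2L
  swap$mouse_id[swap$mouse_id == 99L] <- 3L
  expect_equal(female_fraction(swap, tracks3)$pooled,
               female_fraction(asg3, tracks3)$pooled)
})

test_that("parameter recovery: known female emission rate", {
  set.seed(33)
  tracks <- rbind(
    data.frame(frame = 0:1, time_s = c(0, 100), mouse_id = 1, sex = "F",
               snout_x_mm = -80, snout_y_mm = 0, head_x_mm = -100,
               head_y_mm = 0),
    data.frame(frame = 0:1, time_s = c(0, 100), mouse_id = 2, sex = "M",
               snout_x_mm = 80, snout_y_mm = 0, head_x_mm = 100,
               head_y_mm = 0))
  n <- 400
  emitter <- sample(1:2, n, replace = TRUE, prob = c(0.1, 0.9))
  asg <- data.frame(onset_s = seq(1, 99, length.out = n),
                    offset_s = seq(1, 99, length.out = n) + 0.05,
                    mouse_id = emitter, reason = "assigned")
  ff <- female_fraction(asg, tracks)$pooled
  ci <- qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(ff, ci[1]); expect_lte(ff, ci[2])
})

test_that("dominance split follows vocalization counts", {
  lab <- classify_dominance(c(a = 90, b = 10, f = 30),
                            c(a = "M", b = "M", f = "F"))
  expect_equal(lab, c(a = "dominant", b = "subordinate"))
  expect_null(classify_dominance(c(a = 5, b = 5, f = 2),
                                 c(a = "M", b = "M", f = "F")))
  expect_null(classify_dominance(c(a = 5, f = 2), c(a = "M", f = "F")))
  expect_error(classify_dominance(c(a = NA, b = 1, f = 2),
                                  c(a = "M", b = "M", f = "F")))
})

test_that("nonparametric wrappers dispatch by group count", {
  set.seed(41)
  v <- c(rnorm(10), rnorm(10, 2))
  g2 <- rep(c("x", "y"), each = 10)
  t2 <- usv_group_test(v, g2, n_tests = 6)
  expect_match(t2$method, "Wilcoxon")
  expect_equal(t2$p_adjusted, min(1, t2$p_value * 6))
  g3 <- rep(c("x", "y", "z"), length.out = 20)
  t3 <- usv_group_test(v, g3)
  expect_match(t3$method, "Kruskal")
  tc <- usv_correlation(v, seq_along(v))
  expect_match(tolower(tc$method), "spearman")
})
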