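#' Simulate a complete recording session
#'
#' Convenience wrapper tying the synthetic modules together: pose tracks,
#' USV schedule, and rendered recordings for both microphone sets, fully
#' reproducible from the seed.
#'
#' @param n_mice Number of mice (1-3).
#' @param n_usvs Number of scheduled USVs.
#' @param duration Scene duration (s); default paces USVs ~0.35 s apart.
#' @param profile Interaction profile, see [gen_tracks()].
#' @param band_snr_db In-band SNR (dB), `Inf` = noise-free.
#' @param seed RNG seed (one seed drives tracks, schedule and rendering).
#' @param f_range,dur_range USV sweep frequency / duration ranges.
#' @param scene Scene geometry.
#' @param emitter_probs Optional per-mouse emission probabilities.
#' @param ... Passed to [render_scene()] (e.g. clock parameters).
#' @return A `usv_bundle`.
#' @export
simulate_scene <- function(n_mice = 2, n_usvs = 50,
                           duration = max(10, ceiling(n_usvs * 0.35) + 1),
                           profile = "close", band_snr_db = 10, seed = 1,
                           f_range = c(50000, 80000),
                           dur_range = c(0.04, 0.06),
                           scene = default_scene(),
                           emitter_probs = NULL, ...) {
  set.seed(seed)
  tracks <- gen_tracks(n_mice, duration, profile = profile, scene = scene)
  schedule <- gen_usv_schedule(n_usvs, duration,
                               emitters = seq_len(n_mice),
                               f_range = f_range, dur_range = dur_range,
                               emitter_probs = emitter_probs)
  render_scene(tracks, schedule, scene, band_snr_db = band_snr_db, ...)
}

#' Detect and localize every USV in a bundle
#'
#' Runs the acoustic front half of the pipeline: band-pass the peripheral
#' recording, recover the clock map from the synchronization clicks, detect
#' USVs, estimate each USV's frequency band and energy, then localize each
#' USV with the 64-channel array (coarse-to-fine beamforming) and the
#' four-microphone origin-curve method.
#'
#' @param bundle A `usv_bundle` (from [simulate_scene()] or loaded data).
#' @param methods Character subset of `c("cam64", "slim")`.
#' @param n_freq_max Beamforming frequency bins per USV.
#' @param snippet_pad Seconds of context around each USV used for TDOA
#'   (must exceed the array aperture travel time).
#' @param detect_args Extra arguments for [detect_usvs()]. The pipeline
#'   default uses a 256-sample detector hop (~1 ms frames): detection only
#'   needs ~ms onset precision, while the per-USV band estimation below
#'   keeps the finer 128-sample hop.
#' @return List: `segments` (onset/offset/f_lo/f_hi/energy),
#'   `cam_estimates`, `slim_estimates` (lists parallel to segments),
#'   `clock` (fitted `clock_map`).
#' @export
localize_bundle <- function(bundle, methods = c("cam64", "slim"),
                            n_freq_max = 32, snippet_pad = 0.003,
                            detect_args = list(hop = 256)) {
  scene <- bundle$scene
  fs <- scene$sample_rate
  usm_f <- bandpass_usm4(bundle$usm4)

  # clock map from detected clicks on both streams
  clicks_usm <- detect_clicks(usm_f)
  click_blocks <- Filter(function(b) identical(b$kind, "click"),
                         bundle$cam64)
  clicks_cam <- sort(vapply(click_blocks, block_click_time, numeric(1)))
  clock <- if (length(clicks_cam) == 2)
    align_clocks(clicks_usm, clicks_cam)
  else align_clocks(c(0, 1), c(0, 1))   # identity fallback

  segments <- do.call(detect_usvs,
                      c(list(usm_f, exclude_times = clicks_usm),
                        detect_args))
  n <- nrow(segments)
  segments$f_lo_hz <- NA_real_; segments$f_hi_hz <- NA_real_
  segments$energy <- NA_real_
  cam_est <- vector("list", n); slim_est <- vector("list", n)

  tau_coarse <- NULL
  if ("cam64" %in% methods) {
    g <- beamform_grid(scene, 10)
    tau_coarse <- delay_matrix(as.matrix(expand.grid(x = g$x, y = g$y)),
                               scene$arrays$cam64$mic_positions,
                               scene$platform$z_plane,
                               scene$speed_of_sound)
  }
  sgrid <- if ("slim" %in% methods) slim_grid(scene) else NULL

  for (i in seq_len(n)) {
    on <- segments$onset_s[i]; off <- segments$offset_s[i]
    snip_u <- extract_window(usm_f, on, off, pad = snippet_pad)
    ch_best <- which.max(colSums(snip_u^2))
    sp <- stft_power(snip_u[, ch_best], fs, 512, 128)
    band <- tryCatch(estimate_usv_band(sp), error = function(e)
      c(f_lo = 30000, f_hi = 95000))
    segments$f_lo_hz[i] <- band[1]; segments$f_hi_hz[i] <- band[2]
    segments$energy[i] <- usv_energy(snip_u, fs, band)

    if ("cam64" %in% methods) {
      snip_c <- extract_block_window(bundle$cam64, clock$map(on),
                                     clock$map(off))
      cam_est[[i]] <- localize_cam64(snip_c, band, scene,
                                     n_freq_max = n_freq_max,
                                     tau_coarse = tau_coarse)
    }
    if ("slim" %in% methods)
      slim_est[[i]] <- localize_slim(snip_u, scene, grid = sgrid,
                                     band = band)
  }
  list(segments = segments,
       cam_estimates = if ("cam64" %in% methods) cam_est else NULL,
       slim_estimates = if ("slim" %in% methods) slim_est else NULL,
       clock = clock)
}

#' @noRd
min_snout_separation <- function(tracks, t) {
  pose <- pose_at(tracks, t)
  if (nrow(pose) < 2) return(Inf)
  min(stats::dist(pose[, c("snout_x_mm", "snout_y_mm")]))
}

#' @noRd
match_ground_truth <- function(segments, ground_truth) {
  vapply(seq_len(nrow(segments)), function(i) {
    tmid <- (segments$onset_s[i] + segments$offset_s[i]) / 2
    hit <- which(ground_truth$onset <= tmid & ground_truth$offset >= tmid)
    if (length(hit)) return(hit[1])
    d <- abs((ground_truth$onset + ground_truth$offset) / 2 - tmid)
    if (min(d) < 0.05) which.min(d) else NA_integer_
  }, integer(1))
}

#' Calibrate uncertainties and assign USVs to mice
#'
#' Back half of the pipeline: per-method uncertainty calibration on the
#' far condition (USVs emitted while all snouts were > 100 mm apart, where
#' the nearest mouth is unambiguous), then MPI-based hybrid selection and
#' assignment of every USV. When the bundle carries ground truth, each
#' detected USV is matched to its scheduled emission and localization
#' errors are reported.
#'
#' @param bundle A `usv_bundle`.
#' @param loc Output of [localize_bundle()].
#' @param mouth_f Mouth-model fraction.
#' @param threshold,gate,snr_rule,snr_gate Selection parameters, see
#'   [hybrid_select()].
#' @param far_sep Far-condition separation (mm).
#' @param calibrate Calibrate uncertainty scales on the far condition
#'   (`TRUE`) or take raw uncertainties as mm.
#' @param scales Optional named vector `c(cam = , slim = )` of
#'   pre-computed calibration scales (e.g. pooled over several trials);
#'   overrides `calibrate`.
#' @return List: `assignments` (table with ground-truth columns when
#'   available), `scales`, `summary` (n_detected, n_assigned,
#'   assigned_fraction, mae_mm, correct_emitter_rate).
#' @export
assign_bundle <- function(bundle, loc, mouth_f = 0.02, threshold = 0.95,
                          gate = 50, snr_rule = FALSE, snr_gate = 5,
                          far_sep = 100, calibrate = TRUE, scales = NULL) {
  segments <- loc$segments
  tracks <- bundle$tracks
  n <- nrow(segments)
  tmid <- (segments$onset_s + segments$offset_s) / 2
  minsep <- vapply(tmid, function(t) min_snout_separation(tracks, t),
                   numeric(1))

  resid_far <- function(est_list) {
    vapply(seq_len(n), function(i) {
      est <- est_list[[i]]
      if (minsep[i] <= far_sep || is.null(est) || !isTRUE(est$ok))
        return(NA_real_)
      pose <- pose_at(tracks, tmid[i])
      mo <- mouth_point(as.matrix(pose[, c("snout_x_mm", "snout_y_mm")]),
                        as.matrix(pose[, c("head_x_mm", "head_y_mm")]),
                        mouth_f)
      min(sqrt((mo[, 1] - est$origin[1])^2 + (mo[, 2] - est$origin[2])^2))
    }, numeric(1))
  }
  raw_unc <- function(est_list) {
    vapply(est_list, function(e)
      if (!is.null(e) && isTRUE(e$ok)) e$uncertainty else NA_real_,
      numeric(1))
  }
  if (is.null(scales)) {
    scales <- c(cam = 1, slim = 1)
    if (calibrate && n > 0) {
      for (m in c("cam", "slim")) {
        el <- if (m == "cam") loc$cam_estimates else loc$slim_estimates
        if (is.null(el)) next
        fr <- resid_far(el); ru <- raw_unc(el)
        if (sum(is.finite(fr)) >= 3 && sum(is.finite(ru)) >= 3)
          scales[m] <- calibrate_sigma(ru, fr[is.finite(fr)])
      }
    }
  }

  assignments <- assign_dataset(segments, loc$cam_estimates,
                                loc$slim_estimates, tracks,
                                mouth_f = mouth_f,
                                scale_cam = scales["cam"],
                                scale_slim = scales["slim"],
                                threshold = threshold, gate = gate,
                                snr_rule = snr_rule, snr_gate = snr_gate)
  assignments$min_snout_sep_mm <- minsep

  if (!is.null(bundle$ground_truth) && nrow(bundle$ground_truth)) {
    gi <- match_ground_truth(segments, bundle$ground_truth)
    gt <- bundle$ground_truth[gi, ]
    assignments$gt_usv_id <- gt$usv_id
    assignments$gt_emitter <- gt$emitter
    assignments$error_mm <- sqrt((assignments$est_x - gt$source_x)^2 +
                                 (assignments$est_y - gt$source_y)^2)
  }

  asg <- assignments$reason == "assigned"
  summary <- list(
    n_detected = n, n_assigned = sum(asg),
    assigned_fraction = if (n) sum(asg) / n else NA_real_,
    mae_mm = if (!is.null(assignments$error_mm) && any(asg))
      median(assignments$error_mm[asg], na.rm = TRUE) else NA_real_,
    correct_emitter_rate =
      if (!is.null(assignments$gt_emitter) && any(asg))
        mean(assignments$mouse_id[asg] == assignments$gt_emitter[asg],
             na.rm = TRUE) else NA_real_,
    scales = scales)
  list(assignments = assignments, scales = scales, summary = summary)
}

#' Spatial-vocalization analysis of an assignment table
#'
#' Builds the relative polar occurrence map of receiver mice around
#' emitters over all assigned USVs, plus per-mouse counts.
#'
#' @param assignments Assignment table.
#' @param tracks Pose tracks.
#' @param receiver_marker Receiver marker column prefix (`"snout"` or
#'   `"head"`): relative maps for other body parts reuse the machinery.
#' @param r_max,dr,da Binning, see [polar_histogram()].
#' @return List: `points` (r, alpha per assigned USV-receiver pair),
#'   `histogram`, `per_mouse_counts`.
#' @export
analyze_assignments <- function(assignments, tracks,
                                receiver_marker = "snout",
                                r_max = 200, dr = 10, da = 10) {
  a <- assignments[assignments$reason == "assigned", , drop = FALSE]
  pts <- list()
  for (i in seq_len(nrow(a))) {
    tmid <- (a$onset_s[i] + a$offset_s[i]) / 2
    pose <- pose_at(tracks, tmid)
    em <- pose[pose$mouse_id == a$mouse_id[i], ]
    if (!nrow(em)) next
    for (k in pose$mouse_id[pose$mouse_id != a$mouse_id[i]]) {
      rc <- pose[pose$mouse_id == k, ]
      rp <- relative_polar(
        c(em$snout_x_mm, em$snout_y_mm),
        c(em$head_x_mm, em$head_y_mm),
        c(rc[[paste0(receiver_marker, "_x_mm")]],
          rc[[paste0(receiver_marker, "_y_mm")]]))
      pts[[length(pts) + 1L]] <- data.frame(r = rp[1], alpha = rp[2],
                                            emitter = a$mouse_id[i],
                                            receiver = k)
    }
  }
  pts <- if (length(pts)) do.call(rbind, pts)
         else data.frame(r = numeric(), alpha = numeric(),
                         emitter = integer(), receiver = integer())
  list(points = pts,
       histogram = polar_histogram(pts$r, pts$alpha, r_max, dr, da),
       per_mouse_counts = table(factor(a$mouse_id,
                                       levels = sort(unique(tracks$mouse_id)))))
}
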