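#' Simulate and localize a multi-trial study
#'
#' Runs several independent recording trials (each a full synthetic scene:
#' tracks, schedule, rendering, detection, localization), discarding the
#' audio after each trial so that arbitrarily large studies fit in memory;
#' USVs are pooled across trials exactly as real recordings pool USVs
#' across sessions. Per-method uncertainty calibration is performed on the
#' pooled far-condition residuals (all snouts > `far_sep` apart).
#'
#' @param n_trials Number of trials.
#' @param usvs_per_trial Scheduled USVs per trial.
#' @param n_mice,profile,band_snr_db,f_range,dur_range See
#'   [simulate_scene()].
#' @param seed Base seed; trial `k` uses `seed + k`.
#' @param mouth_f Mouth-model fraction.
#' @param far_sep Far-condition separation (mm).
#' @return A `usv_study`: list with `trials` (each holding `tracks`,
#'   `ground_truth`, `loc`), `scales` (pooled calibration), and the study
#'   parameters.
#' @export
run_localization_study <- function(n_trials = 4, usvs_per_trial = 50,
                                   n_mice = 2, profile = "close",
                                   band_snr_db = 10, seed = 1,
                                   f_range = c(50000, 80000),
                                   dur_range = c(0.04, 0.06),
                                   mouth_f = 0.02, far_sep = 100) {
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    b <- simulate_scene(n_mice = n_mice, n_usvs = usvs_per_trial,
                        profile = profile, band_snr_db = band_snr_db,
                        seed = seed + k, f_range = f_range,
                        dur_range = dur_range)
    loc <- localize_bundle(b)
    trials[[k]] <- list(tracks = b$tracks, ground_truth = b$ground_truth,
                        scene = b$scene, loc = loc)
    rm(b); gc(FALSE)
  }
  # pooled per-method calibration on the far condition
  raw <- list(cam = numeric(), slim = numeric())
  farres <- list(cam = numeric(), slim = numeric())
  for (tr in trials) {
    seg <- tr$loc$segments
    if (!nrow(seg)) next
    tmid <- (seg$onset_s + seg$offset_s) / 2
    minsep <- vapply(tmid, function(t) min_snout_separation(tr$tracks, t),
                     numeric(1))
    for (m in c("cam", "slim")) {
      el <- if (m == "cam") tr$loc$cam_estimates else tr$loc$slim_estimates
      if (is.null(el)) next
      for (i in seq_along(el)) {
        e <- el[[i]]
        if (is.null(e) || !isTRUE(e$ok)) next
        raw[[m]] <- c(raw[[m]], e$uncertainty)
        if (minsep[i] > far_sep) {
          pose <- pose_at(tr$tracks, tmid[i])
          mo <- mouth_point(
            as.matrix(pose[, c("snout_x_mm", "snout_y_mm")]),
            as.matrix(pose[, c("head_x_mm", "head_y_mm")]), mouth_f)
          farres[[m]] <- c(farres[[m]],
                           min(sqrt((mo[, 1] - e$origin[1])^2 +
                                    (mo[, 2] - e$origin[2])^2)))
        }
      }
    }
  }
  scales <- c(cam = 1, slim = 1)
  for (m in c("cam", "slim"))
    if (length(raw[[m]]) >= 3 && length(farres[[m]]) >= 3)
      scales[m] <- calibrate_sigma(raw[[m]], farres[[m]])
  structure(list(trials = trials, scales = scales, mouth_f = mouth_f,
                 far_sep = far_sep, seed = seed,
                 params = list(n_trials = n_trials,
                               usvs_per_trial = usvs_per_trial,
                               n_mice = n_mice, profile = profile,
                               band_snr_db = band_snr_db)),
            class = "usv_study")
}

#' Assign a localized study, optionally restricted to one method
#'
#' Applies the calibrated MPI-based hybrid assignment to every trial of a
#' study and pools the assignment tables. Restricting `methods` re-runs
#' the assignment with the other localizer disabled (the localization
#' itself is reused), which is how single-method accuracies are evaluated.
#'
#' @param study A `usv_study` from [run_localization_study()].
#' @param methods Subset of `c("cam64", "slim")`.
#' @param threshold,gate See [hybrid_select()].
#' @return List: `assignments` (pooled, with `trial` column), `summary`
#'   (as in [assign_bundle()], pooled).
#' @export
assign_study <- function(study, methods = c("cam64", "slim"),
                         threshold = 0.95, gate = 50) {
  out <- vector("list", length(study$trials))
  for (k in seq_along(study$trials)) {
    tr <- study$trials[[k]]
    loc <- tr$loc
    if (!"cam64" %in% methods) loc$cam_estimates <- NULL
    if (!"slim" %in% methods) loc$slim_estimates <- NULL
    res <- assign_bundle(
      list(tracks = tr$tracks, ground_truth = tr$ground_truth),
      loc, mouth_f = study$mouth_f, threshold = threshold, gate = gate,
      far_sep = study$far_sep, scales = study$scales)
    a <- res$assignments
    if (nrow(a)) a$trial <- k
    out[[k]] <- a
  }
  assignments <- do.call(rbind, out)
  asg <- assignments$reason == "assigned"
  summary <- list(
    n_detected = nrow(assignments), n_assigned = sum(asg),
    assigned_fraction = if (nrow(assignments)) mean(asg) else NA_real_,
    mae_mm = if (any(asg)) median(assignments$error_mm[asg], na.rm = TRUE)
             else NA_real_,
    correct_emitter_rate = if (any(asg))
      mean(assignments$mouse_id[asg] == assignments$gt_emitter[asg],
           na.rm = TRUE) else NA_real_,
    scales = study$scales)
  list(assignments = assignments, summary = summary)
}

#' Speaker-style calibration study on a regular grid of static sources
#'
#' Emulates a speaker-calibration experiment: single chirp sources are
#' placed on a regular grid of platform positions, rendered noise-free to
#' the 64-channel array, and localized with the coarse-to-fine beamformer.
#'
#' @param nx,ny Grid dimensions over the platform interior.
#' @param scene Scene geometry.
#' @param f_start,f_end,duration Chirp parameters.
#' @param margin Distance (mm) kept from the platform edges.
#' @return Data frame: true x/y, estimated x/y, error_mm.
#' @export
speaker_grid_study <- function(nx = 5, ny = 5, scene = default_scene(),
                               f_start = 55000, f_end = 75000,
                               duration = 0.05, margin = 30) {
  hx <- scene$platform$length_x / 2 - margin
  hy <- scene$platform$length_y / 2 - margin
  pts <- expand.grid(x = seq(-hx, hx, length.out = nx),
                     y = seq(-hy, hy, length.out = ny))
  fs <- scene$sample_rate
  wav <- synth_chirp(f_start, f_end, duration, fs)
  mics <- scene$arrays$cam64$mic_positions
  g <- beamform_grid(scene, 10)
  tau <- delay_matrix(as.matrix(expand.grid(x = g$x, y = g$y)), mics,
                      scene$platform$z_plane, scene$speed_of_sound)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    src <- c(pts$x[i], pts$y[i], scene$platform$z_plane)
    rec <- propagate_to_mics(wav, src, mics, fs, scene$speed_of_sound)
    est <- localize_cam64(rec$samples, c(f_start - 5000, f_end + 5000),
                          scene, tau_coarse = tau)
    data.frame(true_x = pts$x[i], true_y = pts$y[i],
               est_x = est$origin[1], est_y = est$origin[2],
               error_mm = sqrt(sum((est$origin - src[1:2])^2)))
  })
  do.call(rbind, res)
}
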