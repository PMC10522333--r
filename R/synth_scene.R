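#' @noRd
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Apply a (possibly fractional) time delay to a waveform
#'
#' FFT phase-shift implementation: exact for band-limited signals, needed
#' because time differences of arrival across a planar array at 250 kHz
#' differ by fractions of a sample. The output buffer must be long enough
#' that the delayed signal does not wrap.
#'
#' @param x Numeric waveform.
#' @param delay_s Delay in seconds (positive shifts the signal later).
#' @param fs Sample rate (Hz).
#' @param n_out Output length (>= length(x) + delay in samples).
#' @return Numeric vector of length `n_out`.
#' @export
frac_delay <- function(x, delay_s, fs, n_out = length(x)) {
  if (n_out < length(x)) stop("'n_out' must be >= length(x)")
  # work at a highly composite length (prime-length DFTs are O(n^2))
  N <- stats::nextn(n_out, c(2, 3, 5))
  xp <- c(x, numeric(N - length(x)))
  f <- fft_freqs(N, fs)
  ph <- exp(-2i * pi * f * delay_s)
  if (N %% 2 == 0) ph[N / 2 + 1] <- Re(ph[N / 2 + 1])
  y <- Re(fft(fft(xp) * ph, inverse = TRUE)) / N
  y[seq_len(n_out)]
}

#' Synthesize a USV-like frequency sweep
#'
#' Generates a unit-peak frequency-modulated chirp emulating a mouse
#' ultrasonic vocalization: a smooth sweep from `f_start` to `f_end` with
#' raised-cosine onset/offset tapers (>= 1 ms) to avoid spectral splatter.
#'
#' @param f_start,f_end Start / end frequency (Hz), in (0, Nyquist).
#' @param duration Duration in seconds.
#' @param sample_rate Sample rate (Hz).
#' @param shape `"linear"` (constant sweep rate) or `"logistic"`
#'   (sigmoidal frequency trajectory, steepness 8).
#' @param taper Taper length in seconds (default 1 ms).
#' @return Numeric vector of `round(duration * sample_rate)` samples,
#'   peak absolute amplitude 1.
#' @export
synth_chirp <- function(f_start, f_end, duration, sample_rate = 250000,
                        shape = c("linear", "logistic"), taper = 0.001) {
  shape <- match.arg(shape)
  nyq <- sample_rate / 2
  if (duration <= 0) stop("'duration' must be positive")
  if (min(f_start, f_end) <= 0 || max(f_start, f_end) >= nyq)
    stop("chirp frequencies must lie in (0, Nyquist)")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  finst <- switch(shape,
    linear = f_start + (f_end - f_start) * t / duration,
    logistic = f_start + (f_end - f_start) /
      (1 + exp(-8 * (t / duration - 0.5))))
  phase <- 2 * pi * cumsum(finst) / sample_rate
  x <- sin(phase)
  nt <- max(1L, round(min(taper, duration / 2) * sample_rate))
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nt) - 0.5) / nt))
  x[seq_len(nt)] <- x[seq_len(nt)] * ramp
  x[n + 1 - seq_len(nt)] <- x[n + 1 - seq_len(nt)] * ramp
  x / max(abs(x))
}

#' Propagate a point-source waveform to every microphone of an array
#'
#' Forward model of the localization geometry: each channel receives the
#' source waveform delayed by the straight-line travel time (sub-sample
#' fractional delay via FFT phase shift) and scaled by spherical spreading
#' `ref_dist / r`, with `ref_dist` = 100 mm so amplitudes stay O(1).
#'
#' @param waveform Source waveform (numeric).
#' @param source Length-3 position (mm).
#' @param mic_positions `n x 3` matrix of microphone positions (mm).
#' @param sample_rate Sample rate (Hz).
#' @param c_mm_s Speed of sound (mm/s).
#' @param ref_dist Reference distance (mm) at which gain is 1.
#' @param pad Extra output samples beyond waveform + max delay.
#' @return A `usv_recording`: list with `samples` (samples x channels
#'   matrix), `fs`, `t0` (time of first sample, source-emission clock).
#' @export
propagate_to_mics <- function(waveform, source, mic_positions,
                              sample_rate = 250000, c_mm_s = SPEED_OF_SOUND,
                              ref_dist = 100, pad = 64L) {
  tau <- propagation_delay(source, mic_positions, c_mm_s)
  r <- tau * c_mm_s
  n_out <- length(waveform) + ceiling(max(tau) * sample_rate) + pad
  samples <- vapply(seq_len(nrow(mic_positions)), function(m) {
    (ref_dist / r[m]) * frac_delay(waveform, tau[m], sample_rate, n_out)
  }, numeric(n_out))
  structure(list(samples = samples, fs = sample_rate, t0 = 0),
            class = "usv_recording")
}

#' @noRd
in_band_power <- function(samples, fs, band) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  N <- stats::nextn(n, c(2, 3, 5))
  f <- abs(fft_freqs(N, fs))
  mask <- f >= band[1] & f <= band[2]
  pw <- vapply(seq_len(ncol(samples)), function(ch) {
    X <- fft(c(samples[, ch], numeric(N - n)))
    # Parseval with zero padding: mean square over the original n samples
    sum(Mod(X[mask])^2) / (as.numeric(N) * n)
  }, numeric(1))
  mean(pw)
}

#' Generate sensor noise shaped like each microphone technology
#'
#' `cam64` emulates MEMS microphones whose noise floor rises with frequency:
#' flat below a knee (60 kHz) and +6 dB/octave (power) above it. `usm4`
#' emulates condenser microphones with a flat in-band noise floor.
#'
#' @param n,n_channels Samples and channels to generate.
#' @param fs Sample rate (Hz).
#' @param model `"cam64"` or `"usm4"`.
#' @param knee Knee frequency (Hz) for the rising MEMS noise floor.
#' @return `n x n_channels` matrix of unit-variance-ish shaped noise.
#' @export
shaped_noise <- function(n, n_channels, fs, model = c("cam64", "usm4"),
                         knee = 60000) {
  model <- match.arg(model)
  if (model == "usm4") return(matrix(rnorm(n * n_channels), n, n_channels))
  N <- stats::nextn(n, c(2, 3, 5))
  f <- abs(fft_freqs(N, fs))
  gain <- ifelse(f > knee, f / knee, 1)   # +6 dB/octave power above knee
  vapply(seq_len(n_channels), function(ch) {
    X <- fft(rnorm(N)) * gain
    if (N %% 2 == 0) X[N / 2 + 1] <- Re(X[N / 2 + 1])
    Re(fft(X, inverse = TRUE))[seq_len(n)] / N
  }, numeric(n))
}

#' Add technology-specific sensor noise at a target in-band SNR
#'
#' The in-band SNR is the ratio of mean per-channel signal power to mean
#' per-channel noise power, both restricted to `band`. Noise level is common
#' to all channels (a sensor noise floor does not depend on the source), so
#' the target is met for the array average.
#'
#' @param recording A `usv_recording`.
#' @param model `"cam64"` (rising MEMS floor) or `"usm4"` (flat).
#' @param band_snr_db Target in-band SNR in dB; `Inf` disables noise.
#' @param band Length-2 analysis band (Hz).
#' @param noise_power Optional: directly prescribe the per-channel in-band
#'   noise power, overriding `band_snr_db` (used when one noise level must
#'   be shared across several recording blocks).
#' @return The recording with noise added.
#' @export
add_sensor_noise <- function(recording, model = c("cam64", "usm4"),
                             band_snr_db = 10, band = c(30000, 110000),
                             noise_power = NULL) {
  model <- match.arg(model)
  if (is.null(noise_power) && !is.finite(band_snr_db)) return(recording)
  n <- nrow(recording$samples); nch <- ncol(recording$samples)
  noise <- shaped_noise(n, nch, recording$fs, model)
  np_raw <- in_band_power(noise, recording$fs, band)
  if (is.null(noise_power)) {
    sp <- in_band_power(recording$samples, recording$fs, band)
    noise_power <- sp / 10^(band_snr_db / 10)
  }
  recording$samples <- recording$samples + noise * sqrt(noise_power / np_raw)
  recording
}

#' @noRd
smooth_gauss <- function(n, span) {
  k <- max(3L, as.integer(span) %/% 2L * 2L + 1L)
  x <- rnorm(n + 2L * k)
  w <- stats::dnorm(seq(-3, 3, length.out = k)); w <- w / sum(w)
  y <- stats::filter(x, w, sides = 2)
  y <- y[(k + 1):(k + n)]
  as.numeric((y - mean(y)) / sd(y))
}

#' Generate smooth synthetic mouse pose tracks
#'
#' Random smooth trajectories on the interaction platform emulating
#' interacting mice: mouse 1 wanders freely; the other mice hold a smoothly
#' varying distance to mouse 1 whose stationary distribution is set by the
#' interaction profile. `"close"` keeps most frames within 100 mm
#' snout-snout distance (close social contact); `"far"` keeps the animals
#' mostly more than 100 mm apart (the low-confusion regime used for
#' uncertainty calibration). The snout leads the head centre by ~20 mm along
#' the heading, so the gaze vector is never degenerate.
#'
#' @param n_mice 1, 2 or 3.
#' @param duration Track duration (s).
#' @param frame_rate Video frame rate (Hz), default 55.6 (18 ms frames).
#' @param profile `"close"` or `"far"`.
#' @param seed Optional RNG seed for reproducibility.
#' @param sexes Character vector of sexes per mouse; default one female
#'   plus males (the courtship pairings the setup records).
#' @param scene Scene geometry (platform bounds).
#' @return Data frame: frame, time_s, mouse_id, sex, snout_x_mm, snout_y_mm,
#'   head_x_mm, head_y_mm.
#' @export
gen_tracks <- function(n_mice = 2, duration = 60, frame_rate = 55.6,
                       profile = c("close", "far"), seed = NULL,
                       sexes = NULL, scene = default_scene()) {
  profile <- match.arg(profile)
  if (!n_mice %in% 1:3) stop("'n_mice' must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sexes)) sexes <- c("F", "M", "M")[seq_len(n_mice)]
  nf <- floor(duration * frame_rate) + 1L
  tsec <- (seq_len(nf) - 1) / frame_rate
  hx <- scene$platform$length_x / 2 - 25
  hy <- scene$platform$length_y / 2 - 25
  span <- round(frame_rate)  # ~1 s smoothing: calm exploratory gait

  base_walk <- function(half) half * tanh(cumsum(rnorm(nf, sd = 2.2)) / half)
  snout <- vector("list", n_mice)
  snout[[1]] <- cbind(base_walk(hx), base_walk(hy))
  if (n_mice > 1) {
    for (k in 2:n_mice) {
      z <- abs(smooth_gauss(nf, span))
      d <- if (profile == "close") 15 + 60 * z else 120 + 100 * z
      phi <- cumsum(rnorm(nf, sd = 0.03)) + runif(1, 0, 2 * pi)
      p <- snout[[1]] + d * cbind(cos(phi), sin(phi))
      p[, 1] <- pmin(pmax(p[, 1], -hx), hx)
      p[, 2] <- pmin(pmax(p[, 2], -hy), hy)
      snout[[k]] <- p
    }
  }
  out <- lapply(seq_len(n_mice), function(k) {
    p <- snout[[k]]
    v <- rbind(diff(p), c(0, 0))
    for (i in seq_len(nf)[-1])  # carry heading through stationary frames
      if (sqrt(sum(v[i, ]^2)) < 1e-6) v[i, ] <- v[i - 1, ]
    if (sqrt(sum(v[1, ]^2)) < 1e-6) v[1, ] <- c(1, 0)
    h <- v / sqrt(rowSums(v^2))
    head <- p - 20 * h
    data.frame(frame = seq_len(nf) - 1L, time_s = tsec, mouse_id = k,
               sex = sexes[k], snout_x_mm = p[, 1], snout_y_mm = p[, 2],
               head_x_mm = head[, 1], head_y_mm = head[, 2])
  })
  do.call(rbind, out)
}

#' Schedule synthetic USV emissions
#'
#' Draws onsets (uniform, non-overlapping spacing), durations, frequency
#' sweeps and emitters for a synthetic scene. Defaults emulate the common
#' mouse USV repertoire (sweeps within 30-110 kHz, 20-80 ms).
#'
#' @param n_usvs Number of USVs.
#' @param duration Scene duration (s); onsets are spread over
#'   `[0.5, duration - 0.5]`.
#' @param emitters Vector of mouse ids to draw emitters from.
#' @param f_range Length-2 range (Hz) the sweep endpoints are drawn from.
#' @param dur_range Length-2 range (s) of USV durations.
#' @param amp_range Source amplitude range.
#' @param seed Optional RNG seed.
#' @param emitter_probs Optional emission probability per entry of
#'   `emitters`.
#' @return Data frame: usv_id, emitter, onset, duration, f_start, f_end,
#'   amplitude, shape.
#' @export
gen_usv_schedule <- function(n_usvs, duration, emitters = 1:2,
                             f_range = c(50000, 80000),
                             dur_range = c(0.04, 0.06),
                             amp_range = c(0.7, 1), seed = NULL,
                             emitter_probs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_usvs == 0)
    return(data.frame(usv_id = integer(), emitter = integer(),
                      onset = numeric(), duration = numeric(),
                      f_start = numeric(), f_end = numeric(),
                      amplitude = numeric(), shape = character()))
  slots <- seq(0.5, duration - 0.5, length.out = n_usvs)
  onset <- slots + runif(n_usvs, 0, 0.4 * diff(range(slots)) / max(1, n_usvs - 1))
  dur <- runif(n_usvs, dur_range[1], dur_range[2])
  f1 <- runif(n_usvs, f_range[1], f_range[2])
  f2 <- pmin(pmax(f1 + runif(n_usvs, -15000, 15000), f_range[1]), f_range[2])
  data.frame(usv_id = seq_len(n_usvs),
             emitter = sample(emitters, n_usvs, replace = TRUE,
                              prob = emitter_probs),
             onset = onset, duration = dur, f_start = f1, f_end = f2,
             amplitude = runif(n_usvs, amp_range[1], amp_range[2]),
             shape = "linear", stringsAsFactors = FALSE)
}

#' @noRd
click_waveform <- function(fs) {
  synth_chirp(25000, 115000, 0.0008, fs, taper = 0.0002)
}

#' @noRd
interp_track <- function(tracks, mouse, t) {
  tr <- tracks[tracks$mouse_id == mouse, ]
  c(x = approx(tr$time_s, tr$snout_x_mm, t, rule = 2)$y,
    y = approx(tr$time_s, tr$snout_y_mm, t, rule = 2)$y)
}

#' Render a full synthetic acoustic scene
#'
#' Produces ground-truthed recordings for both microphone sets. The
#' 4-channel peripheral (usm4) recording is one continuous stream on the
#' reference clock. The 64-channel array (cam64) is rendered as triggered
#' recording blocks around each USV plus two click blocks, mirroring
#' data-rate-limited array acquisition; each block carries its start time on
#' the cam64 clock, which runs at `t_cam = clock_offset + clock_drift * t`.
#' Two synchronization click transients are inserted near the start and end
#' of the trial on both recordings. Each USV is emitted from the emitting
#' mouse's snout position at the USV temporal midpoint, on the beamforming
#' plane (z = 10 mm).
#'
#' @param tracks Pose tracks from [gen_tracks()].
#' @param schedule USV schedule from [gen_usv_schedule()].
#' @param scene Scene geometry.
#' @param band_snr_db In-band SNR (dB) for both arrays; `Inf` = noise-free.
#' @param seed Optional RNG seed.
#' @param clock_offset,clock_drift Cam64 clock model parameters.
#' @param block_margin Seconds of cam64 audio kept on each side of a USV.
#' @return A `usv_bundle` list: `scene`, `tracks`, `schedule`,
#'   `ground_truth` (usv_id, emitter, onset, offset, f_start, f_end,
#'   source_x/y/z, overlapped), `usm4` recording, `cam64` block list,
#'   `clock` (true offset/drift), click times on both clocks.
#' @export
render_scene <- function(tracks, schedule, scene = default_scene(),
                         band_snr_db = 10, seed = NULL,
                         clock_offset = 0.0123, clock_drift = 1.00001,
                         block_margin = 0.025) {
  if (!is.null(seed)) set.seed(seed)
  fs <- scene$sample_rate
  duration <- max(max(tracks$time_s),
                  if (nrow(schedule)) max(schedule$onset + schedule$duration)
                  else 1) + 0.3
  click_t <- c(0.05, duration - 0.1)
  usm_mics <- scene$arrays$usm4$mic_positions
  cam_mics <- scene$arrays$cam64$mic_positions
  cc <- scene$speed_of_sound
  snr_band <- if (nrow(schedule))
    range(c(schedule$f_start, schedule$f_end)) else c(30000, 110000)

  n_usm <- ceiling(duration * fs)
  usm <- matrix(0, n_usm, nrow(usm_mics))

  gt <- schedule
  gt$offset <- gt$onset + gt$duration
  gt$source_x <- rep(NA_real_, nrow(gt))
  gt$source_y <- rep(NA_real_, nrow(gt))
  gt$source_z <- rep(scene$platform$z_plane, nrow(gt))
  cam_blocks <- list()

  # first pass: sources, waveforms, in-band signal power *during* a USV
  # (the SNR target refers to signal-occupied samples, not the silence
  # between calls)
  n_ev <- nrow(schedule)
  wavs <- vector("list", n_ev)
  srcs <- matrix(NA_real_, n_ev, 3)
  sp_cam <- numeric(n_ev); sp_usm <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    ev <- schedule[i, ]
    tmid <- ev$onset + ev$duration / 2
    src2 <- interp_track(tracks, ev$emitter, tmid)
    srcs[i, ] <- c(src2[1], src2[2], scene$platform$z_plane)
    gt$source_x[i] <- srcs[i, 1]; gt$source_y[i] <- srcs[i, 2]
    wavs[[i]] <- ev$amplitude * synth_chirp(ev$f_start, ev$f_end,
                                            ev$duration, fs,
                                            shape = ev$shape)
    wp <- in_band_power(wavs[[i]], fs, snr_band)
    r_cam <- propagation_delay(srcs[i, ], cam_mics, cc) * cc
    r_usm <- propagation_delay(srcs[i, ], usm_mics, cc) * cc
    sp_cam[i] <- wp * mean((100 / r_cam)^2)
    sp_usm[i] <- wp * mean((100 / r_usm)^2)
  }
  npow_cam <- if (is.finite(band_snr_db) && n_ev)
    mean(sp_cam) / 10^(band_snr_db / 10) else 0
  npow_usm <- if (is.finite(band_snr_db) && n_ev)
    mean(sp_usm) / 10^(band_snr_db / 10) else 0

  # second pass: render cam64 blocks (signal steering + shaped noise
  # composed in the frequency domain, one inverse FFT per channel)
  knee <- 60000
  for (i in seq_len(n_ev)) {
    ev <- schedule[i, ]
    wav <- wavs[[i]]
    tau <- propagation_delay(srcs[i, ], cam_mics, cc)
    r <- tau * cc
    n_blk <- length(wav) + ceiling((2 * block_margin + max(tau)) * fs) + 64
    N <- stats::nextn(n_blk, c(2, 3, 5))
    Xw <- fft(c(wav, numeric(N - length(wav))))
    f <- fft_freqs(N, fs)
    gain <- ifelse(abs(f) > knee, abs(f) / knee, 1)
    bmask <- abs(f) >= snr_band[1] & abs(f) <= snr_band[2]
    samples <- matrix(0, n_blk, nrow(cam_mics))
    for (m in seq_len(nrow(cam_mics))) {
      Xs <- Xw * exp(-2i * pi * f * (tau[m] + block_margin)) * (100 / r[m])
      if (npow_cam > 0) {
        Z <- (rnorm(N) + 1i * rnorm(N)) * gain
        zp <- sum(Mod(Z[bmask])^2) / (2 * as.numeric(N)^2)
        Xs <- Xs + Z * sqrt(npow_cam / zp)
      }
      samples[, m] <- Re(fft(Xs, inverse = TRUE))[seq_len(n_blk)] / N
    }
    cam_blocks[[length(cam_blocks) + 1L]] <-
      structure(list(samples = samples, fs = fs,
                     t0 = clock_offset + clock_drift *
                       (ev$onset - block_margin),
                     usv_id = ev$usv_id, kind = "usv"),
                class = "usv_recording")
    # --- usm4: add into the continuous buffer, fractional onset folded
    #     into the propagation delay
    i0 <- floor(ev$onset * fs)
    dt0 <- ev$onset - i0 / fs
    tau_u <- propagation_delay(srcs[i, ], usm_mics, cc) + dt0
    n_out <- length(wav) + ceiling(max(tau_u) * fs) + 64
    for (m in seq_len(nrow(usm_mics))) {
      y <- (100 / ((tau_u[m] - dt0) * cc)) *
        frac_delay(wav, tau_u[m], fs, n_out)
      idx <- i0 + seq_len(n_out)
      keep <- idx <= n_usm & idx >= 1
      usm[idx[keep], m] <- usm[idx[keep], m] + y[keep]
    }
  }

  # overlap flag on ground truth
  gt$overlapped <- rep(FALSE, nrow(gt))
  if (nrow(gt) > 1) {
    o <- order(gt$onset)
    for (j in seq_along(o)[-1])
      if (gt$onset[o[j]] < gt$offset[o[j - 1]]) {
        gt$overlapped[o[j]] <- TRUE; gt$overlapped[o[j - 1]] <- TRUE
      }
  }

  # --- synchronization clicks (same transient on every channel, no
  #     propagation: the click is presented adjacent to the sensors)
  clk <- click_waveform(fs)
  for (tc in click_t) {
    idx <- floor(tc * fs) + seq_along(clk)
    usm[idx, ] <- usm[idx, ] + 2 * matrix(clk, length(clk), ncol(usm))
    blk <- matrix(0, length(clk) + 2000, nrow(cam_mics))
    blk[1000 + seq_along(clk), ] <- 2 * clk
    cb <- structure(list(samples = blk, fs = fs,
                         t0 = clock_offset + clock_drift * (tc - 1000 / fs),
                         usv_id = NA_integer_, kind = "click"),
                    class = "usv_recording")
    if (npow_cam > 0)
      cb <- add_sensor_noise(cb, "cam64", band = snr_band,
                             noise_power = npow_cam)
    cam_blocks[[length(cam_blocks) + 1L]] <- cb
  }

  # --- usm4 flat sensor noise at the analytic level for the target SNR
  if (npow_usm > 0) {
    sigma <- sqrt(npow_usm * (fs / 2) / (snr_band[2] - snr_band[1]))
    usm <- usm + matrix(rnorm(length(usm), sd = sigma), nrow(usm))
  }
  usm_rec <- structure(list(samples = usm, fs = fs, t0 = 0),
                       class = "usv_recording")

  structure(list(scene = scene, tracks = tracks, schedule = schedule,
                 ground_truth = gt, usm4 = usm_rec, cam64 = cam_blocks,
                 clock = c(offset = clock_offset, drift = clock_drift),
                 click_times_usm4 = click_t,
                 click_times_cam64 = clock_offset + clock_drift * click_t,
                 duration = duration),
            class = "usv_bundle")
}

#' @export
print.usv_bundle <- function(x, ...) {
  cat(sprintf(
    "usv_bundle: %.1f s, %d mice, %d scheduled USVs, %d cam64 blocks\n",
    x$duration, length(unique(x$tracks$mouse_id)), nrow(x$schedule),
    length(x$cam64)))
  invisible(x)
}
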