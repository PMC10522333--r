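#' Band-pass filter a peripheral-microphone recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass between 30 and
#' 110 kHz, total filter order 20, applied to every channel. Zero-phase
#' filtering preserves USV onset/offset timing, which downstream TDOA
#' estimation depends on.
#'
#' @param recording A `usv_recording` (continuous multichannel samples).
#' @param f_lo,f_hi Band edges (Hz).
#' @param order Total band-pass filter order (even).
#' @return The filtered recording.
#' @export
bandpass_usm4 <- function(recording, f_lo = 30000, f_hi = 110000,
                          order = 20) {
  fs <- recording$fs
  if (fs < 250000) stop("sample rate must be >= 250 kHz")
  bf <- signal::butter(order / 2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  recording$samples <- apply(recording$samples, 2,
                             function(x) signal::filtfilt(bf, x))
  recording
}

#' Affine clock map between two recording streams
#'
#' Fits `t_b = offset + drift * t_a` exactly through the two
#' synchronization-click pairs presented at the start and end of a trial.
#'
#' @param click_times_a,click_times_b Two click times per stream (s).
#' @return A `clock_map` list: `offset` (s), `drift` (dimensionless, ~1),
#'   plus `map(t)` and `inverse(t)` functions.
#' @export
align_clocks <- function(click_times_a, click_times_b) {
  stopifnot(length(click_times_a) == 2, length(click_times_b) == 2)
  da <- diff(click_times_a)
  if (abs(da) < 1e-9) stop("coincident clicks: degenerate clock fit")
  drift <- diff(click_times_b) / da
  offset <- click_times_b[1] - drift * click_times_a[1]
  structure(list(offset = offset, drift = drift,
                 map = function(t) offset + drift * t,
                 inverse = function(t) (t - offset) / drift),
            class = "clock_map")
}

#' Detect synchronization clicks in a recording
#'
#' Finds the times of the two strongest isolated broadband transients
#' (the start/end synchronization clicks) from the smoothed squared
#' envelope averaged over channels.
#'
#' @param recording A `usv_recording`.
#' @param min_sep Minimum separation between the two clicks (s).
#' @return Two click times (s), on the recording's own clock.
#' @export
detect_clicks <- function(recording, min_sep = 1) {
  fs <- recording$fs
  env <- smoothed_envelope(recording$samples, fs)
  i1 <- which.max(env)
  mask <- abs(seq_along(env) - i1) > min_sep * fs
  i2 <- which(mask)[which.max(env[mask])]
  sort(c(i1, i2) - 1) / fs + recording$t0
}

# smoothed squared envelope shared by every click-time estimator, so click
# times on different streams carry the same (cancelling) group delay
#' @noRd
smoothed_envelope <- function(samples, fs) {
  env <- rowMeans(as.matrix(samples)^2)
  k <- round(2e-4 * fs)
  env <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  env[is.na(env)] <- 0
  env
}

#' Click time within one triggered recording block
#'
#' @param block A `usv_recording` block containing a synchronization click.
#' @return Click time (s) on the block's clock.
#' @export
block_click_time <- function(block) {
  env <- smoothed_envelope(block$samples, block$fs)
  block$t0 + (which.max(env) - 1) / block$fs
}

#' Short-time power spectrogram
#'
#' Hann-windowed FFT frames; the workhorse for detection and per-USV
#' frequency-band estimation (512-sample FFT, 75% overlap at 250 kHz gives
#' ~488 Hz x 0.5 ms resolution).
#'
#' @param x Numeric waveform.
#' @param fs Sample rate (Hz).
#' @param nfft Frame/FFT length.
#' @param hop Hop size in samples.
#' @return List: `power` (nfft/2+1 x nframes), `freqs` (Hz),
#'   `times` (frame-centre times, s).
#' @export
stft_power <- function(x, fs, nfft = 512, hop = nfft / 4) {
  n <- length(x)
  if (n < nfft) x <- c(x, numeric(nfft - n))
  starts <- seq(1, max(1, length(x) - nfft + 1), by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  fr <- vapply(starts, function(s) x[s:(s + nfft - 1)] * win,
               numeric(nfft))
  sp <- mvfft(fr)[1:(nfft / 2 + 1), , drop = FALSE]
  list(power = Mod(sp)^2, freqs = (0:(nfft / 2)) * fs / nfft,
       times = (starts - 1 + nfft / 2) / fs)
}

#' Detect ultrasonic vocalizations on the peripheral microphones
#'
#' Spectrogram band-energy detector with hysteresis: per channel, the
#' 30-110 kHz band energy per frame is compared against a robust noise
#' floor (median + k * MAD); candidate segments must exceed the high
#' threshold somewhere and are extended over the low threshold, then
#' segments shorter than `min_dur` are dropped and gaps shorter than
#' `merge_gap` merged. A vocalization is kept if detected on at least one
#' of the channels (per-channel segments are interval-unioned).
#'
#' This detector is deliberately simple plumbing for synthetic and
#' well-conditioned recordings; it is not a re-implementation of
#' specialised USV detection software.
#'
#' @param recording Band-pass filtered `usv_recording`.
#' @param band Detection band (Hz).
#' @param k_high,k_low Hysteresis thresholds in robust-MAD units.
#' @param min_dur Minimum segment duration (s).
#' @param merge_gap Maximum gap to merge (s).
#' @param nfft,hop Spectrogram parameters.
#' @param exclude_times Times (s) to blank out (e.g. synchronization
#'   clicks), each with `exclude_halfwidth` seconds on both sides.
#' @param exclude_halfwidth Half-width of each exclusion window (s).
#' @param chunk_s Processing chunk length (s), bounds memory.
#' @return Data frame of segments: onset_s, offset_s (recording clock).
#' @export
detect_usvs <- function(recording, band = c(30000, 110000),
                        k_high = 10, k_low = 4,
                        min_dur = 0.005, merge_gap = 0.010,
                        nfft = 512, hop = 128,
                        exclude_times = numeric(),
                        exclude_halfwidth = 0.005, chunk_s = 10) {
  fs <- recording$fs
  n <- nrow(recording$samples)
  nch <- ncol(recording$samples)
  all_int <- matrix(numeric(0), 0, 2)
  for (ch in seq_len(nch)) {
    e <- numeric(0); tt <- numeric(0)
    starts <- seq(1, n, by = round(chunk_s * fs))
    for (s0 in starts) {
      s1 <- min(n, s0 + round(chunk_s * fs) + nfft - 1)
      sp <- stft_power(recording$samples[s0:s1, ch], fs, nfft, hop)
      bm <- sp$freqs >= band[1] & sp$freqs <= band[2]
      e <- c(e, colSums(sp$power[bm, , drop = FALSE]))
      tt <- c(tt, sp$times + (s0 - 1) / fs)
    }
    for (tc in exclude_times)
      e[abs(tt - tc) < exclude_halfwidth] <- NA
    med <- median(e, na.rm = TRUE)
    madv <- median(abs(e - med), na.rm = TRUE) * 1.4826
    hi <- med + k_high * madv
    lo <- med + k_low * madv
    above_lo <- !is.na(e) & e > lo
    r <- rle(above_lo)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1
    for (j in which(r$values)) {
      idx <- begs[j]:ends[j]
      if (any(e[idx] > hi, na.rm = TRUE))
        all_int <- rbind(all_int, c(tt[begs[j]], tt[ends[j]]))
    }
  }
  if (nrow(all_int) == 0)
    return(data.frame(onset_s = numeric(), offset_s = numeric()))
  # union across channels, then merge small gaps
  all_int <- all_int[order(all_int[, 1]), , drop = FALSE]
  merged <- all_int[1, , drop = FALSE]
  for (j in seq_len(nrow(all_int))[-1]) {
    if (all_int[j, 1] <= merged[nrow(merged), 2] + merge_gap)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], all_int[j, 2])
    else merged <- rbind(merged, all_int[j, ])
  }
  keep <- (merged[, 2] - merged[, 1]) >= min_dur
  merged <- merged[keep, , drop = FALSE]
  data.frame(onset_s = merged[, 1] + recording$t0,
             offset_s = merged[, 2] + recording$t0)
}

#' @noRd
band_from_peaks <- function(peak_freqs) {
  q <- unname(quantile(peak_freqs, c(0.10, 0.90)))
  f_lo <- q[1] - 5000
  f_hi <- min(q[2] + 5000, 95000)
  if (f_hi - f_lo > 50000) f_lo <- 45000
  c(f_lo = max(f_lo, 1000), f_hi = f_hi)
}

#' Per-USV analysis frequency band
#'
#' Estimates the frequency range of one USV from its spectrogram: the
#' 10th-90th percentile of the per-frame most intense frequency, broadened
#' by 5 kHz at both ends, capped at 95 kHz at the top (above which the
#' array's MEMS microphones are noise-dominated); if the broadened range
#' exceeds 50 kHz the lower end is reset to 45 kHz. Beamforming is then
#' restricted to this band.
#'
#' @param power Spectrogram power matrix (bins x frames) of the segment,
#'   or a list as returned by [stft_power()].
#' @param freqs Bin frequencies (Hz) (ignored when `power` is a list).
#' @param search_band Frequencies considered when picking per-frame peaks.
#' @return Named vector `c(f_lo, f_hi)` in Hz.
#' @export
estimate_usv_band <- function(power, freqs = NULL,
                              search_band = c(25000, 120000)) {
  if (is.list(power)) { freqs <- power$freqs; power <- power$power }
  if (is.null(dim(power)) || ncol(power) < 1 || nrow(power) < 2)
    stop("degenerate spectrogram")
  sel <- freqs >= search_band[1] & freqs <= search_band[2]
  pk <- freqs[sel][apply(power[sel, , drop = FALSE], 2, which.max)]
  band_from_peaks(pk)
}

#' In-band RMS energy of a USV
#'
#' Mean across channels of the root-mean-square amplitude of the snippet
#' restricted (by FFT masking) to the USV's frequency band. Used downstream
#' as the per-USV vocalization intensity.
#'
#' @param snippets Samples x channels matrix covering the USV.
#' @param fs Sample rate (Hz).
#' @param band Length-2 band (Hz).
#' @return Scalar RMS.
#' @export
usv_energy <- function(snippets, fs, band) {
  snippets <- as.matrix(snippets)
  n <- nrow(snippets)
  N <- stats::nextn(n, c(2, 3, 5))
  f <- abs(fft_freqs(N, fs))
  mask <- f >= band[1] & f <= band[2]
  rms <- vapply(seq_len(ncol(snippets)), function(ch) {
    X <- fft(c(snippets[, ch], numeric(N - n)))
    X[!mask] <- 0
    sqrt(mean(Re(fft(X, inverse = TRUE) / N)[seq_len(n)]^2))
  }, numeric(1))
  mean(rms)
}

#' Extract a time window from a continuous recording
#'
#' @param recording A `usv_recording`.
#' @param t_on,t_off Window (s) on the recording clock.
#' @param pad Extra seconds kept on each side.
#' @return Samples x channels matrix.
#' @export
extract_window <- function(recording, t_on, t_off, pad = 0) {
  fs <- recording$fs
  i0 <- max(1L, floor((t_on - pad - recording$t0) * fs) + 1L)
  i1 <- min(nrow(recording$samples),
            ceiling((t_off + pad - recording$t0) * fs))
  if (i1 <= i0) stop("window outside recording")
  recording$samples[i0:i1, , drop = FALSE]
}

#' Extract a USV window from triggered array blocks
#'
#' Finds the recording block containing the interval (block and query both
#' on the array clock) and returns the corresponding samples.
#'
#' @param blocks List of `usv_recording` blocks.
#' @param t_on,t_off Window (s) on the block clock.
#' @return Samples x channels matrix, or `NULL` if no block covers the
#'   interval.
#' @export
extract_block_window <- function(blocks, t_on, t_off) {
  for (b in blocks) {
    if (identical(b$kind, "click")) next
    t1 <- b$t0 + nrow(b$samples) / b$fs
    if (t_on >= b$t0 && t_off <= t1) {
      i0 <- floor((t_on - b$t0) * b$fs) + 1L
      i1 <- min(nrow(b$samples), ceiling((t_off - b$t0) * b$fs))
      return(b$samples[i0:i1, , drop = FALSE])
    }
  }
  NULL
}
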