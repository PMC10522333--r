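# Independent oracles used to validate the package's signal paths.
# These deliberately use the crudest correct method available (integer-
# sample time-domain operations, direct definitions) and never call the
# implementation they check.

# Brute-force time-domain delay-and-sum: for each candidate node, advance
# every channel by its propagation delay and accumulate the power of the
# coherent sum. TDOAs across the aperture differ by fractions of a sample
# at 250 kHz, so fractional shifts use a Hann-windowed sinc kernel (exact
# to ~1e-3 for band-limited signals); whole-sample rounding or linear
# interpolation would misrank near-tied nodes on small arrays.
td_delay_sum_oracle <- function(snippets, fs, mic_positions, nodes,
                                z_plane, c_mm_s) {
  n <- nrow(snippets)
  half <- 8L
  shift_by <- function(x, lag) {
    l0 <- floor(lag); fr <- lag - l0
    xp <- c(x, numeric(2L * half + 2L))
    idx <- seq_len(n) + l0
    y <- numeric(n)
    for (k in -half:half) {
      u <- k - fr
      h <- if (abs(u) < 1e-12) 1 else sin(pi * u) / (pi * u)
      h <- h * 0.5 * (1 + cos(pi * k / (half + 1)))
      j <- pmin(pmax(idx + k, 1L), n + 2L * half + 2L)
      y <- y + h * xp[j]
    }
    y
  }
  vapply(seq_len(nrow(nodes)), function(g) {
    d <- sqrt((nodes[g, 1] - mic_positions[, 1])^2 +
              (nodes[g, 2] - mic_positions[, 2])^2 +
              (z_plane - mic_positions[, 3])^2)
    lag <- d / c_mm_s * fs
    lag <- lag - min(lag)
    acc <- numeric(n)
    for (m in seq_len(ncol(snippets)))
      acc <- acc + shift_by(snippets[, m], lag[m])
    sum(acc^2)
  }, numeric(1))
}

# Spectrogram ridge: per-frame argmax frequency of a plain Hann STFT,
# written out longhand.
ridge_oracle <- function(x, fs, nfft = 512, hop = 128) {
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
  freqs <- (0:(nfft / 2)) * fs / nfft
  vapply(starts, function(s) {
    X <- stats::fft(x[s:(s + nfft - 1)] * win)[1:(nfft / 2 + 1)]
    freqs[which.max(Mod(X))]
  }, numeric(1))
}

# Averaged-periodogram PSD (Welch with rectangular segments), direct
# definition.
psd_oracle <- function(x, fs, nseg = 4096) {
  nwin <- floor(length(x) / nseg)
  acc <- numeric(nseg / 2 + 1)
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1) * nseg + 1):(w * nseg)]
    X <- stats::fft(seg)[1:(nseg / 2 + 1)]
    acc <- acc + Mod(X)^2 / nseg
  }
  list(psd = acc / nwin, freqs = (0:(nseg / 2)) * fs / nseg)
}

# Band-limited mean-square via the averaged periodogram (Parseval),
# independent of the package's FFT-mask implementation.
band_power_oracle <- function(x, fs, band, nseg = 4096) {
  p <- psd_oracle(x, fs, nseg)
  sel <- p$freqs >= band[1] & p$freqs <= band[2]
  # one-sided: double all bins except DC/Nyquist
  w <- ifelse(p$freqs[sel] %in% c(0, fs / 2), 1, 2)
  sum(w * p$psd[sel]) / nseg
}

# Integer-lag cross-correlation TDOA (no interpolation, no weighting).
xcorr_tdoa_oracle <- function(x_i, x_j, fs, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(x_i[(1 + l):length(x_i)] *
                    x_j[1:(length(x_j) - l)])
    else sum(x_i[1:(length(x_i) + l)] * x_j[(1 - l):length(x_j)])
  }, numeric(1))
  # positive lag: x_i lags x_j by that many samples
  lags[which.max(cc)] / fs
}

# Small rendered test scene shared across files (built once per run).
tiny_scene_cache <- new.env()
get_tiny_bundle <- function() {
  if (is.null(tiny_scene_cache$bundle)) {
    tiny_scene_cache$bundle <- simulate_scene(
      n_mice = 2, n_usvs = 6, band_snr_db = 10, seed = 42)
  }
  tiny_scene_cache$bundle
}
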