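#' Per-channel spectra of a USV snippet at the beamforming frequencies
#'
#' FFT of the whole segment (rectangular window); the frequency set is the
#' FFT bins inside the USV band, evenly subsampled to at most `n_freq_max`
#' bins (the steered-response sum converges well before every bin of a
#' 40-60 ms segment is used).
#'
#' @param snippets Samples x channels matrix.
#' @param fs Sample rate (Hz).
#' @param band Length-2 USV band (Hz).
#' @param n_freq_max Maximum number of frequency bins.
#' @return List: `S` (nfreq x nchannel complex), `freqs` (Hz).
#' @export
segment_spectra <- function(snippets, fs, band, n_freq_max = 48) {
  snippets <- as.matrix(snippets)
  # zero-pad to a highly composite length: a prime-length DFT is O(n^2)
  n <- stats::nextn(nrow(snippets), c(2, 3, 5))
  if (n > nrow(snippets))
    snippets <- rbind(snippets,
                      matrix(0, n - nrow(snippets), ncol(snippets)))
  X <- mvfft(snippets)
  f <- (seq_len(n) - 1) * (fs / n)
  idx <- which(f >= band[1] & f <= band[2] & f <= fs / 2)
  if (length(idx) == 0) stop("no FFT bins inside the USV band")
  if (length(idx) > n_freq_max)
    idx <- idx[unique(round(seq(1, length(idx), length.out = n_freq_max)))]
  list(S = X[idx, , drop = FALSE], freqs = f[idx])
}

#' Propagation-delay matrix for a set of grid nodes
#'
#' @param grid_xy Nodes x 2 matrix of planar coordinates (mm).
#' @param mic_positions Mics x 3 matrix (mm).
#' @param z_plane Source plane height (mm).
#' @param c_mm_s Speed of sound (mm/s).
#' @return Nodes x mics matrix of delays (s).
#' @export
delay_matrix <- function(grid_xy, mic_positions, z_plane,
                         c_mm_s = SPEED_OF_SOUND) {
  dx <- outer(grid_xy[, 1], mic_positions[, 1], "-")
  dy <- outer(grid_xy[, 2], mic_positions[, 2], "-")
  dz <- matrix(z_plane - mic_positions[, 3], nrow(grid_xy),
               nrow(mic_positions), byrow = TRUE)
  sqrt(dx^2 + dy^2 + dz^2) / c_mm_s
}

#' Density of sound origin (steered-response power) over grid nodes
#'
#' Delay-and-sum beamforming in the frequency domain: for every candidate
#' node the per-channel spectra are steered by `exp(+i 2 pi f tau)` --
#' conjugate-cancelling the propagation delays of a source at that node --
#' summed over microphones, and the power accumulated over the band:
#' `DSO(x, y) = sum_f | sum_m S_m(f) exp(+i 2 pi f tau(m, x, y)) |^2`.
#' Values are non-negative by construction; uniform channel weights.
#'
#' @param spectra List from [segment_spectra()] (`S`, `freqs`).
#' @param grid_xy Nodes x 2 matrix (mm); ignored if `tau` is given.
#' @param mic_positions Mics x 3 matrix (mm); ignored if `tau` is given.
#' @param z_plane Source plane (mm).
#' @param c_mm_s Speed of sound (mm/s).
#' @param tau Optional precomputed nodes x mics delay matrix (s).
#' @return Numeric vector of DSO values, one per node.
#' @export
compute_dso <- function(spectra, grid_xy = NULL, mic_positions = NULL,
                        z_plane = 10, c_mm_s = SPEED_OF_SOUND, tau = NULL) {
  if (length(spectra$freqs) == 0) stop("empty frequency set")
  if (is.null(tau))
    tau <- delay_matrix(grid_xy, mic_positions, z_plane, c_mm_s)
  S <- spectra$S
  if (!is.complex(S)) S <- S + 0i
  dso_scan(S, as.numeric(spectra$freqs), tau)
}

#' @noRd
make_field <- function(grid, values, scene) {
  nx <- length(grid$x); ny <- length(grid$y)
  vm <- matrix(values, nx, ny)
  pk <- arrayInd(which.max(vm), dim(vm))
  structure(list(grid = grid, values = vm,
                 peak = c(x = grid$x[pk[1]], y = grid$y[pk[2]]),
                 centroid = NULL, snr = NULL),
            class = "sound_field")
}

#' Coarse beamforming scan over the full surface
#'
#' First stage of the two-step localization: DSO over the whole extended
#' platform surface (500 x 400 mm) at 10 mm spacing on the plane 1 cm above
#' the platform, with the field SNR attached.
#'
#' @param snippets Samples x channels matrix (cam64 snippet of one USV).
#' @param band Length-2 USV band (Hz).
#' @param scene Scene geometry.
#' @param spacing Grid spacing (mm).
#' @param n_freq_max Frequency bins used.
#' @param tau Optional precomputed delay matrix for the coarse grid
#'   (cacheable across USVs: the grid is scene-fixed).
#' @return A `sound_field` with `peak` and `snr`.
#' @export
coarse_scan <- function(snippets, band, scene = default_scene(),
                        spacing = 10, n_freq_max = 48, tau = NULL,
                        spectra = NULL) {
  grid <- beamform_grid(scene, spacing)
  nodes <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  sp <- if (is.null(spectra))
    segment_spectra(snippets, scene$sample_rate, band, n_freq_max)
  else spectra
  v <- compute_dso(sp, nodes, scene$arrays$cam64$mic_positions,
                   scene$platform$z_plane, scene$speed_of_sound, tau = tau)
  fld <- make_field(grid, v, scene)
  fld$snr <- snr_cam64(fld)
  fld
}

#' Fine beamforming scan with weighted-centroid origin
#'
#' Second stage: 1 mm grid over a 30 x 30 mm window (31 x 31 nodes,
#' inclusive endpoints) centred on the coarse peak, clipped at the surface
#' boundary. The DSO-weighted centroid of the window (raw weights, no
#' thresholding) is the USV origin.
#'
#' @param snippets,band,scene,n_freq_max As in [coarse_scan()].
#' @param center Length-2 window centre (mm), normally the coarse peak.
#' @param halfwidth Window half-width (mm).
#' @param spacing Fine spacing (mm).
#' @return A `sound_field` with `centroid`.
#' @export
fine_scan <- function(snippets, band, center, scene = default_scene(),
                      halfwidth = 15, spacing = 1, n_freq_max = 48,
                      spectra = NULL) {
  hx <- scene$platform$length_x / 2 + scene$platform$beamform_margin
  hy <- scene$platform$length_y / 2 + scene$platform$beamform_margin
  gx <- seq(center[1] - halfwidth, center[1] + halfwidth, by = spacing)
  gy <- seq(center[2] - halfwidth, center[2] + halfwidth, by = spacing)
  gx <- gx[gx >= -hx & gx <= hx]
  gy <- gy[gy >= -hy & gy <= hy]
  grid <- list(x = gx, y = gy, spacing = spacing)
  nodes <- as.matrix(expand.grid(x = gx, y = gy))
  sp <- if (is.null(spectra))
    segment_spectra(snippets, scene$sample_rate, band, n_freq_max)
  else spectra
  v <- compute_dso(sp, nodes, scene$arrays$cam64$mic_positions,
                   scene$platform$z_plane, scene$speed_of_sound)
  fld <- make_field(grid, v, scene)
  w <- fld$values / sum(fld$values)
  fld$centroid <- c(x = sum(outer(gx, rep(1, length(gy))) * w),
                    y = sum(outer(rep(1, length(gx)), gy) * w))
  fld
}

#' Field signal-to-noise ratio of a beamforming scan
#'
#' `SNR = max(DSO) / sd(DSO)` over all nodes of the (coarse, full-surface)
#' field. Scale-invariant; its inverse serves as the raw localization
#' uncertainty. A zero-variance field returns `Inf` with a warning and is
#' flagged unusable downstream.
#'
#' @param field A `sound_field` (or a numeric vector/matrix of DSO values).
#' @return Scalar SNR.
#' @export
snr_cam64 <- function(field) {
  v <- if (inherits(field, "sound_field")) field$values else field
  if (length(v) < 2) stop("need >= 2 grid nodes")
  s <- sd(as.numeric(v))
  if (s == 0) {
    warning("zero-variance DSO field; SNR undefined (degenerate)")
    return(Inf)
  }
  max(v) / s
}

#' Localize one USV with the 64-channel array
#'
#' Full two-step beamforming: coarse scan over the surface, fine scan
#' centred on the coarse peak, origin = DSO-weighted centroid of the fine
#' window, uncertainty = 1 / field SNR (raw; calibrated to mm downstream).
#' The SNR is retained for the optional "array if SNR > 5" selection
#' variant.
#'
#' @param snippets Samples x channels cam64 snippet, or `NULL` when the
#'   USV fell outside the array recording (returns a no-estimate result).
#' @param band USV band (Hz).
#' @param scene Scene geometry.
#' @param n_freq_max Frequency bins used per scan.
#' @param tau_coarse Optional cached coarse-grid delay matrix.
#' @return A `localization_estimate`: list(origin, uncertainty, snr,
#'   method = "cam64", ok), or `ok = FALSE` when no estimate is possible.
#' @export
localize_cam64 <- function(snippets, band, scene = default_scene(),
                           n_freq_max = 48, tau_coarse = NULL) {
  if (is.null(snippets) || nrow(snippets) < 8)
    return(structure(list(ok = FALSE, method = "cam64"),
                     class = "localization_estimate"))
  sp <- segment_spectra(snippets, scene$sample_rate, band, n_freq_max)
  co <- coarse_scan(snippets, band, scene, n_freq_max = n_freq_max,
                    tau = tau_coarse, spectra = sp)
  if (!is.finite(co$snr))
    return(structure(list(ok = FALSE, method = "cam64"),
                     class = "localization_estimate"))
  fi <- fine_scan(snippets, band, co$peak, scene, n_freq_max = n_freq_max,
                  spectra = sp)
  structure(list(ok = TRUE, origin = fi$centroid,
                 uncertainty = 1 / co$snr, snr = co$snr,
                 method = "cam64"),
            class = "localization_estimate")
}

#' @export
print.localization_estimate <- function(x, ...) {
  if (!isTRUE(x$ok)) cat(sprintf("localization_estimate[%s]: none\n",
                                 x$method))
  else cat(sprintf(
    "localization_estimate[%s]: (%.1f, %.1f) mm, uncertainty %.3g%s\n",
    x$method, x$origin[1], x$origin[2], x$uncertainty,
    if (!is.null(x$snr)) sprintf(", snr %.1f", x$snr) else ""))
  invisible(x)
}
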