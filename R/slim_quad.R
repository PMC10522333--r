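#' Time difference of arrival between two microphone channels
#'
#' Generalized cross-correlation with PHAT weighting by default (robust for
#' frequency sweeps; plain cross-correlation available), peak search within
#' `+/- max_delay`, parabolic sub-sample interpolation. Positive TDOA means
#' the sound arrives at channel `i` first.
#'
#' @param x_i,x_j Time-aligned snippets (numeric, common clock).
#' @param fs Sample rate (Hz).
#' @param max_delay Physical delay bound (s), >= aperture / c.
#' @param weighting `"phat"` or `"cc"`.
#' @param band Optional length-2 frequency band (Hz); correlation is
#'   restricted to it. Restricting GCC to the USV's own band keeps
#'   noise-dominated frequencies out of the (whitening) PHAT weighting.
#' @param min_peak_ratio Peak must exceed this multiple of the correlation
#'   standard deviation within the search window, else no-estimate (`NA`).
#' @return TDOA in seconds, or `NA_real_` for a flat correlation.
#' @export
pairwise_tdoa <- function(x_i, x_j, fs, max_delay,
                          weighting = c("phat", "cc"), band = NULL,
                          min_peak_ratio = 4) {
  weighting <- match.arg(weighting)
  n <- max(length(x_i), length(x_j))
  N <- 2^ceiling(log2(2 * n))
  Xi <- fft(c(x_i, numeric(N - length(x_i))))
  Xj <- fft(c(x_j, numeric(N - length(x_j))))
  R <- Xi * Conj(Xj)
  if (!is.null(band)) {
    f <- abs(fft_freqs(N, fs))
    R[f < band[1] | f > band[2]] <- 0
  }
  if (weighting == "phat") {
    m <- Mod(R)
    R <- R / pmax(m, max(m) * 1e-12)   # zeroed bins stay zero
  }
  r <- Re(fft(R, inverse = TRUE)) / N
  # circular lag axis: index 1 = lag 0, wrap negative lags from the top
  maxlag <- min(N / 2 - 1, ceiling(max_delay * fs))
  lags <- -maxlag:maxlag
  rv <- r[ifelse(lags >= 0, lags + 1, N + lags + 1)]
  pk <- which.max(rv)
  if (rv[pk] < min_peak_ratio * sd(rv)) return(NA_real_)
  lag <- lags[pk]
  # parabolic refinement
  if (pk > 1 && pk < length(rv)) {
    y1 <- rv[pk - 1]; y2 <- rv[pk]; y3 <- rv[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  # ifft(Xi conj(Xj)) peaks at lag -d when x_j lags x_i by d samples,
  # so negate to make "arrives at i first" positive
  td <- -lag / fs
  max(min(td, max_delay), -max_delay)
}

#' Precomputed accumulation grid for the four-microphone localizer
#'
#' A 1 mm grid over the extended platform surface with the per-microphone
#' source-plane distances cached; building it once per scene avoids
#' recomputing ~200k distances for every USV.
#'
#' @param scene Scene geometry.
#' @param spacing Grid spacing (mm).
#' @return List: `x`, `y`, `spacing`, `dist` (list of per-mic node-distance
#'   vectors), `mics`.
#' @export
slim_grid <- function(scene = default_scene(), spacing = 1) {
  g <- beamform_grid(scene, spacing)
  nodes <- as.matrix(expand.grid(x = g$x, y = g$y))
  mics <- scene$arrays$usm4$mic_positions
  z <- scene$platform$z_plane
  dist <- lapply(seq_len(nrow(mics)), function(m)
    sqrt((nodes[, 1] - mics[m, 1])^2 + (nodes[, 2] - mics[m, 2])^2 +
         (z - mics[m, 3])^2))
  list(x = g$x, y = g$y, spacing = spacing, dist = dist, mics = mics)
}

#' Origin-curve density contribution of one microphone pair
#'
#' A TDOA constrains the source to one branch of a hyperbola of constant
#' range difference `d_j - d_i = c * tdoa` on the source plane. The curve is
#' rasterized onto the accumulation grid as a Gaussian cross-section kernel
#' in range-difference residual (`sigma` = 2 mm). An unphysical TDOA
#' (`|tdoa * c|` exceeding the microphone separation) contributes nothing,
#' with a warning.
#'
#' @param tdoa TDOA in seconds (positive: arrives at mic `i` first).
#' @param i,j Microphone indices into the grid's mic set.
#' @param grid A [slim_grid()].
#' @param c_mm_s Speed of sound (mm/s).
#' @param sigma Kernel width across the curve (mm).
#' @return Numeric density vector over the grid nodes.
#' @export
origin_curve <- function(tdoa, i, j, grid, c_mm_s = SPEED_OF_SOUND,
                         sigma = 2) {
  sep <- sqrt(sum((grid$mics[i, ] - grid$mics[j, ])^2))
  if (abs(tdoa * c_mm_s) >= sep) {
    warning("unphysical TDOA for pair (", i, ",", j, "): no contribution")
    return(numeric(length(grid$dist[[1]])))
  }
  resid <- (grid$dist[[j]] - grid$dist[[i]]) - c_mm_s * tdoa
  exp(-resid^2 / (2 * sigma^2))
}

#' Localize one USV with the four peripheral microphones
#'
#' SLIM-style localization reconstructed from its published summary:
#' pairwise TDOAs (all 6 pairs), per-pair origin curves on the source
#' plane, curves summed into an intersection density, origin = density
#' argmax refined by the centroid of all cells above 90% of the maximum.
#' Uncertainty = standard deviation (RMS spread) of the positions of all
#' cells with density > 0.9 x max, floored at 1 mm. Requires at least 3
#' usable pairs; fewer yields a no-estimate result, which makes the method
#' robust to heavy noise confined to one channel.
#'
#' @param snippets Samples x 4 matrix, channels time-aligned.
#' @param scene Scene geometry.
#' @param grid Optional precomputed [slim_grid()].
#' @param weighting GCC weighting, see [pairwise_tdoa()].
#' @param band Optional USV band (Hz) the correlations are restricted to.
#' @param sigma Curve kernel width (mm).
#' @param min_pairs Minimum usable pairs.
#' @return A `localization_estimate` (`origin`, `uncertainty` in mm,
#'   `n_pairs`, `method = "slim"`, `ok`).
#' @export
localize_slim <- function(snippets, scene = default_scene(), grid = NULL,
                          weighting = "phat", band = NULL, sigma = 2,
                          min_pairs = 3) {
  if (is.null(snippets) || ncol(snippets) < 2)
    return(structure(list(ok = FALSE, method = "slim"),
                     class = "localization_estimate"))
  if (is.null(grid)) grid <- slim_grid(scene)
  mics <- grid$mics
  cc <- scene$speed_of_sound
  fs <- scene$sample_rate
  pairs <- utils::combn(ncol(snippets), 2)
  dens <- numeric(length(grid$dist[[1]]))
  n_used <- 0L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sep <- sqrt(sum((mics[i, ] - mics[j, ])^2))
    td <- pairwise_tdoa(snippets[, i], snippets[, j], fs,
                        max_delay = sep / cc, weighting = weighting,
                        band = band)
    if (is.na(td) || abs(td * cc) >= sep) next
    dens <- dens + origin_curve(td, i, j, grid, cc, sigma)
    n_used <- n_used + 1L
  }
  if (n_used < min_pairs)
    return(structure(list(ok = FALSE, method = "slim", n_pairs = n_used),
                     class = "localization_estimate"))
  nx <- length(grid$x)
  top <- which(dens > 0.9 * max(dens))
  tx <- grid$x[(top - 1) %% nx + 1]
  ty <- grid$y[(top - 1) %/% nx + 1]
  w <- dens[top] / sum(dens[top])
  origin <- c(x = sum(tx * w), y = sum(ty * w))
  # uncertainty: plain (unweighted) spread of the >90% cells
  spread <- sqrt(mean((tx - mean(tx))^2 + (ty - mean(ty))^2))
  structure(list(ok = TRUE, origin = origin,
                 uncertainty = max(spread, 1), n_pairs = n_used,
                 method = "slim"),
            class = "localization_estimate")
}
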