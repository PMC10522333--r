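#' Microphone positions on a Fermat (sunflower) spiral
#'
#' Generates `n` coplanar microphone positions arranged on a Fermat spiral
#' using Vogel's golden-angle parametrization: point `k` sits at angle
#' `k * 137.508...` degrees and radius proportional to `sqrt(k)`, scaled so
#' the outermost microphone lies on the circle of the requested diameter.
#' This is the standard model for a sunflower-packed planar array when the
#' manufacturer's exact coordinates are not available; all downstream
#' algorithms take microphone positions as data, so measured coordinates can
#' be substituted.
#'
#' @param n Number of microphones (>= 1).
#' @param diameter Diameter in mm of the circle enclosing the spiral.
#' @param center Numeric length-3 vector, center of the array (mm). The
#'   spiral lies in the plane `z = center[3]`.
#' @return An `n x 3` matrix of positions (mm), columns `x`, `y`, `z`.
#' @examples
#' pos <- fermat_spiral_positions(64, 160)
#' max(sqrt(pos[, 1]^2 + pos[, 2]^2))  # == 80
#' @export
fermat_spiral_positions <- function(n, diameter, center = c(0, 0, 0)) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer")
  if (length(diameter) != 1L || !is.finite(diameter) || diameter <= 0)
    stop("'diameter' must be positive")
  n <- as.integer(n)
  golden_angle <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  r <- (diameter / 2) * sqrt(k / n)
  theta <- (k - 1L) * golden_angle  # k = 1 at angle 0 by convention
  cbind(x = center[1] + r * cos(theta),
        y = center[2] + r * sin(theta),
        z = rep(center[3], n))
}

#' Acoustic propagation delay between a source and a microphone
#'
#' Straight-line travel time: Euclidean distance divided by the speed of
#' sound. Vectorized over rows when `source` or `mic` are matrices.
#'
#' @param source Numeric length-3 vector or `n x 3` matrix (mm).
#' @param mic Numeric length-3 vector or `n x 3` matrix (mm).
#' @param c_mm_s Speed of sound in mm/s (default 343 m/s, dry air at 20 C).
#' @return Delay(s) in seconds.
#' @export
propagation_delay <- function(source, mic, c_mm_s = SPEED_OF_SOUND) {
  if (!is.finite(c_mm_s) || c_mm_s <= 0) stop("speed of sound must be > 0")
  if (is.null(dim(source))) source <- matrix(source, ncol = 3)
  if (is.null(dim(mic))) mic <- matrix(mic, ncol = 3)
  n <- max(nrow(source), nrow(mic))
  s <- source[rep_len(seq_len(nrow(source)), n), 1:3, drop = FALSE]
  m <- mic[rep_len(seq_len(nrow(mic)), n), 1:3, drop = FALSE]
  unname(sqrt(rowSums((s - m)^2)) / c_mm_s)
}

#' Speed of sound default, mm/s (343 m/s: dry air at 20 C, the housing
#' temperature of the recording booth).
#' @export
SPEED_OF_SOUND <- 343000

#' Default recording-scene geometry
#'
#' Builds the scene configuration of the reference setup: a 40 x 30 cm
#' elevated interaction platform (world origin at its surface centre, x along
#' the 400 mm edge, z up, millimetres), a 64-microphone planar array
#' ("cam64") on a Fermat spiral of ~16 cm diameter mounted 46.5 cm above the
#' platform and shifted 6.52 cm along +x, four peripheral ultrasonic
#' microphones ("usm4") placed 5 cm beyond the platform corners in x and
#' 6 cm in y with membranes 12.1 cm above the surface, and an overhead
#' camera (640 x 512 px, ~0.815 mm/px, shifted 4.48 cm along -x).
#' Beamforming is evaluated on a plane 1 cm above the platform over the
#' platform extended by a 5 cm margin on every edge (500 x 400 mm).
#'
#' @param c_mm_s Speed of sound (mm/s).
#' @param sample_rate Audio sample rate in Hz.
#' @return A list of class `usv_scene`.
#' @export
default_scene <- function(c_mm_s = SPEED_OF_SOUND, sample_rate = 250000) {
  platform <- list(length_x = 400, length_y = 300,
                   beamform_margin = 50, z_plane = 10)
  cam64 <- list(
    label = "cam64",
    mic_positions = fermat_spiral_positions(64, 160, center = c(65.2, 0, 465)),
    aperture = "64-mic MEMS Fermat spiral, 160 mm"
  )
  # corners: 50 mm beyond the 400 mm edge, 60 mm beyond the 300 mm edge
  ux <- platform$length_x / 2 + 50
  uy <- platform$length_y / 2 + 60
  usm4 <- list(
    label = "usm4",
    mic_positions = cbind(x = c(-ux, ux, ux, -ux),
                          y = c(-uy, -uy, uy, uy),
                          z = rep(121, 4)),
    aperture = "4 condenser mics at platform corners"
  )
  camera <- list(offset_x = -44.8, offset_y = 0, mm_per_px = 0.815,
                 image_width = 640, image_height = 512, frame_rate = 55.6)
  structure(list(platform = platform,
                 arrays = list(cam64 = cam64, usm4 = usm4),
                 camera = camera,
                 speed_of_sound = c_mm_s,
                 sample_rate = sample_rate),
            class = "usv_scene")
}

#' @export
print.usv_scene <- function(x, ...) {
  cat("usv_scene:\n")
  cat(sprintf("  platform %g x %g mm, beamform plane z = %g mm (+%g mm margin)\n",
              x$platform$length_x, x$platform$length_y,
              x$platform$z_plane, x$platform$beamform_margin))
  for (a in x$arrays)
    cat(sprintf("  array '%s': %d mics, z = %g..%g mm\n", a$label,
                nrow(a$mic_positions), min(a$mic_positions[, 3]),
                max(a$mic_positions[, 3])))
  cat(sprintf("  fs = %g Hz, c = %g mm/s\n", x$sample_rate, x$speed_of_sound))
  invisible(x)
}

#' Beamforming grid over the extended platform surface
#'
#' Node-centred grid with inclusive endpoints over the platform extended by
#' the beamform margin (default scene: 500 x 400 mm, so a 10 mm grid has
#' 51 x 41 nodes).
#'
#' @param scene A `usv_scene`.
#' @param spacing Grid spacing in mm.
#' @return List with `x`, `y` node coordinate vectors (mm) and `spacing`.
#' @export
beamform_grid <- function(scene, spacing) {
  hx <- scene$platform$length_x / 2 + scene$platform$beamform_margin
  hy <- scene$platform$length_y / 2 + scene$platform$beamform_margin
  list(x = seq(-hx, hx, by = spacing), y = seq(-hy, hy, by = spacing),
       spacing = spacing)
}

#' Convert between world coordinates and grid indices
#'
#' Grid nodes are cell centres; indices are 1-based (column-major over x
#' fastest). Round-trips exactly for all grid nodes.
#' @param grid A grid from [beamform_grid()].
#' @param ix,iy 1-based node indices.
#' @return `grid_to_world`: 2-column matrix of node coordinates.
#' @export
grid_to_world <- function(grid, ix, iy) {
  cbind(x = grid$x[ix], y = grid$y[iy])
}

#' @rdname grid_to_world
#' @param x,y World coordinates (mm).
#' @export
world_to_grid <- function(grid, x, y) {
  cbind(ix = as.integer(round((x - grid$x[1]) / grid$spacing)) + 1L,
        iy = as.integer(round((y - grid$y[1]) / grid$spacing)) + 1L)
}

#' Serialize / restore a scene configuration as JSON
#'
#' All geometry in mm, rates in Hz.
#' @param scene A `usv_scene`.
#' @param path File path.
#' @export
write_scene_json <- function(scene, path) {
  s <- unclass(scene)
  for (nm in names(s$arrays))
    s$arrays[[nm]]$mic_positions <-
      as.data.frame(s$arrays[[nm]]$mic_positions)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_json
#' @export
read_scene_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(s$arrays)) {
    mp <- as.matrix(s$arrays[[nm]]$mic_positions)
    dimnames(mp) <- list(NULL, c("x", "y", "z"))
    s$arrays[[nm]]$mic_positions <- mp
  }
  structure(s, class = "usv_scene")
}
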