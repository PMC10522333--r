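#' Default (identity-like) camera distortion model
#'
#' The correction formulas are fixed by the pipeline but the fitted
#' parameter values are setup-specific; the default model is effectively
#' the identity (very weak radial strength, zero tangential strengths), so
#' synthetic tracks pass through unchanged unless a measured model is
#' configured.
#'
#' @param image_width,image_height Image size (px).
#' @param lambda Radial distortion strength (larger = weaker distortion).
#' @param Zx,Zy Axis zoom factors.
#' @param ax,ay Tangential distortion centre (px).
#' @param kx,ky Tangential distortion strengths.
#' @param px,py Platform size in the undistorted image (px).
#' @param dpx,dpy Platform offset from the image top-left (px).
#' @return A `distortion_model` list.
#' @export
distortion_model <- function(image_width = 640, image_height = 512,
                             lambda = 1e6, Zx = 1, Zy = 1,
                             ax = 320, ay = 256, kx = 0, ky = 0,
                             px = 490, py = 368, dpx = 75, dpy = 72) {
  if (lambda <= 0) stop("'lambda' must be > 0")
  structure(list(x12 = image_width / 2, y12 = image_height / 2,
                 lambda = lambda, Zx = Zx, Zy = Zy, ax = ax, ay = ay,
                 kx = kx, ky = ky, px = px, py = py, dpx = dpx, dpy = dpy,
                 image_width = image_width, image_height = image_height),
            class = "distortion_model")
}

#' Forward radial distortion
#'
#' Evaluates the radial lens model literally:
#' `x_rd = x12 + atan(r/lambda)/(r/lambda) * (x_ru - x12) * Zx` (same for
#' y), where `r` is the distance of the undistorted point to the image
#' centre. The factor `atan(u)/u < 1` pulls points toward the centre; at
#' `r -> 0` it tends to 1 so the centre is a fixed point (up to zoom).
#'
#' @param pt Length-2 undistorted pixel coordinates, or n x 2 matrix.
#' @param model A [distortion_model()].
#' @return Distorted coordinates, same shape.
#' @export
apply_radial <- function(pt, model) {
  p <- rbind(pt)
  rd <- sqrt((p[, 1] - model$x12)^2 + (p[, 2] - model$y12)^2)
  u <- rd / model$lambda
  fac <- ifelse(u < 1e-12, 1, atan(u) / u)
  out <- cbind(model$x12 + fac * (p[, 1] - model$x12) * model$Zx,
               model$y12 + fac * (p[, 2] - model$y12) * model$Zy)
  if (is.null(dim(pt))) drop(out) else out
}

#' Forward tangential distortion
#'
#' Literal evaluation of the tangential model:
#' `x_td = x_tu - (x_tu - ax)/|W - ax| * kx/py * (y_tu - dpy) * Zx` and
#' `y_td = y_tu - (y_tu - ay)/|H - ay| * ky/px * (x_tu - dpx) * Zy`,
#' with `W`, `H` the image size. Zero strengths give the identity.
#'
#' @param pt Length-2 point or n x 2 matrix (undistorted px).
#' @param model A [distortion_model()].
#' @return Distorted coordinates, same shape.
#' @export
apply_tangential <- function(pt, model) {
  p <- rbind(pt)
  out <- cbind(
    p[, 1] - (p[, 1] - model$ax) / abs(model$image_width - model$ax) *
      model$kx / model$py * (p[, 2] - model$dpy) * model$Zx,
    p[, 2] - (p[, 2] - model$ay) / abs(model$image_height - model$ay) *
      model$ky / model$px * (p[, 1] - model$dpx) * model$Zy)
  if (is.null(dim(pt))) drop(out) else out
}

#' Numeric inverses of the distortion maps
#'
#' `invert_radial` solves the scalar radius equation by bisection;
#' `invert_tangential` iterates the forward map as a fixed point. Both
#' round-trip to < 1e-6 px over the image for default-scale parameters.
#'
#' @param pt Distorted pixel coordinates (length-2 or n x 2).
#' @param model A [distortion_model()].
#' @param tol Convergence tolerance (px).
#' @return Undistorted coordinates.
#' @export
invert_radial <- function(pt, model, tol = 1e-9) {
  p <- rbind(pt)
  out <- t(apply(p, 1, function(q) {
    dx <- (q[1] - model$x12) / model$Zx
    dy <- (q[2] - model$y12) / model$Zy
    rd_target <- sqrt(dx^2 + dy^2)
    if (rd_target < 1e-12) return(c(model$x12, model$y12))
    # solve atan(r/l)/(r/l) * r == rd_target for r (monotone increasing)
    f <- function(r) atan(r / model$lambda) / (r / model$lambda) * r -
      rd_target
    hi <- rd_target * 2 + 1
    while (f(hi) < 0) hi <- hi * 2
    r <- stats::uniroot(f, c(rd_target * 0.5, hi), tol = tol)$root
    c(model$x12 + dx * r / rd_target, model$y12 + dy * r / rd_target)
  }))
  if (is.null(dim(pt))) drop(out) else out
}

#' @rdname invert_radial
#' @param max_iter Maximum fixed-point iterations.
#' @export
invert_tangential <- function(pt, model, tol = 1e-9, max_iter = 100) {
  p <- rbind(pt)
  u <- p
  for (it in seq_len(max_iter)) {
    d <- apply_tangential(u, model)
    err <- p - rbind(d)
    u <- u + err
    if (max(abs(err)) < tol) break
  }
  if (is.null(dim(pt))) drop(u) else u
}

#' Convert undistorted pixel coordinates to world millimetres
#'
#' Scales by the effective resolution (~0.815 mm/px) and translates by the
#' camera's lateral offset into the platform-centred world frame. Image
#' convention: origin top-left, y down; world y points up, so the y axis is
#' flipped. The image centre maps to the camera's position over the
#' platform.
#'
#' @param pt Length-2 pixel point or n x 2 matrix.
#' @param scene Scene geometry (camera block).
#' @return World coordinates (mm), same shape.
#' @export
px_to_world <- function(pt, scene = default_scene()) {
  cam <- scene$camera
  p <- rbind(pt)
  out <- cbind(
    cam$offset_x + (p[, 1] - (cam$image_width - 1) / 2) * cam$mm_per_px,
    cam$offset_y - (p[, 2] - (cam$image_height - 1) / 2) * cam$mm_per_px)
  if (is.null(dim(pt))) drop(out) else out
}

#' @rdname px_to_world
#' @export
world_to_px <- function(pt, scene = default_scene()) {
  cam <- scene$camera
  p <- rbind(pt)
  out <- cbind(
    (p[, 1] - cam$offset_x) / cam$mm_per_px + (cam$image_width - 1) / 2,
    -(p[, 2] - cam$offset_y) / cam$mm_per_px + (cam$image_height - 1) / 2)
  if (is.null(dim(pt))) drop(out) else out
}

#' Video frame index at a given audio time
#'
#' Nearest frame-trigger lookup (0-based index); exact midpoints between
#' triggers resolve to the earlier frame.
#'
#' @param time_s Time on the audio clock (s).
#' @param frame_times Strictly increasing frame-trigger times (s).
#' @return Integer frame index (0-based).
#' @export
frame_at <- function(time_s, frame_times) {
  if (time_s < frame_times[1] - 0.5 * diff(frame_times[1:2]) ||
      time_s > frame_times[length(frame_times)] +
        0.5 * diff(frame_times[length(frame_times) - 1:0]))
    stop("time outside the recorded frame clock")
  d <- abs(frame_times - time_s)
  cand <- which(d == min(d))
  cand[1] - 1L
}
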