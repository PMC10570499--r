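# Evaluation geometry. All screen coordinates are mm (origin upper-left);
# the eye sits on the normal through the screen center at the viewing
# distance. Angular quantities are degrees of visual angle.

as_points <- function(p) {
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  if (ncol(p) != 2) stop("points must be (x, y) pairs")
  p
}

#' On-screen distance to the screen center
#'
#' Euclidean distance (mm) from a point to the screen center
#' `(width/2, height/2)`.
#'
#' @param p point(s): length-2 vector or n x 2 matrix, mm.
#' @param geom a [screen_geometry()].
#' @return numeric distance(s) in mm.
#' @export
onscreen_distance <- function(p, geom) {
  p <- as_points(p)
  ctr <- screen_center(geom)
  sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
}

#' Visual angle of an on-screen distance
#'
#' `atan(d / distance)` in degrees, the angle subtended at the eye by a
#' distance `d` measured from the screen center.
#'
#' @param d on-screen distance(s) in mm (non-negative).
#' @param geom a [screen_geometry()].
#' @return angle(s) in degrees.
#' @export
visual_angle <- function(d, geom) {
  if (any(d < 0)) stop("on-screen distance must be non-negative")
  atan(d / geom$distance) * 180 / pi
}

#' Angular separation between two on-screen points
#'
#' The visual angle between the eye-to-point directions of two screen
#' locations, computed from the spherical law of cosines on the slant
#' triangle (eye, p1, p2): with `c_i = cos(visual angle of point i)` and `d`
#' the on-screen distance between the points,
#' \deqn{\cos\gamma = \frac{c_1^2 + c_2^2}{2 c_1 c_2}
#'   - \frac{d^2 c_1 c_2}{2 D^2}}
#' which is exact for an eye on the center normal at distance `D`.
#'
#' @param p1,p2 point(s) in mm: length-2 vectors or n x 2 matrices.
#' @param geom a [screen_geometry()].
#' @return separation(s) in degrees; zero iff the points coincide.
#' @export
angular_separation <- function(p1, p2, geom) {
  p1 <- as_points(p1); p2 <- as_points(p2)
  c1 <- cos(visual_angle(onscreen_distance(p1, geom), geom) * pi / 180)
  c2 <- cos(visual_angle(onscreen_distance(p2, geom), geom) * pi / 180)
  d2 <- (p1[, 1] - p2[, 1])^2 + (p1[, 2] - p2[, 2])^2
  cg <- (c1^2 + c2^2) / (2 * c1 * c2) - d2 * c1 * c2 / (2 * geom$distance^2)
  acos(pmin(1, pmax(-1, cg))) * 180 / pi
}

#' Fixation accuracy in degrees of visual angle
#'
#' Mean, over trials, of the angular separation between each trial's target
#' position and the measured (mean fixation) gaze position.
#'
#' @param targets n x 2 matrix of target positions (mm).
#' @param measured n x 2 matrix of per-trial mean measured positions (mm).
#' @param geom a [screen_geometry()].
#' @return list with `mean_deg` and `per_trial_deg`.
#' @export
gaze_accuracy <- function(targets, measured, geom) {
  targets <- as_points(targets); measured <- as_points(measured)
  if (nrow(targets) == 0L) stop("empty trial set")
  if (nrow(targets) != nrow(measured))
    stop("targets and measured positions differ in trial count")
  per <- angular_separation(targets, measured, geom)
  list(mean_deg = mean(per), per_trial_deg = per)
}

#' Fixation precision in degrees of visual angle
#'
#' Root mean square of the angular separations between successive gaze
#' samples within a fixation: \eqn{\sqrt{\frac{1}{n}\sum_i \theta_i^2}} over
#' the `n` successive sample pairs. Measures reproducibility, not closeness
#' to the target.
#'
#' @param samples m x 2 matrix of successive gaze samples (mm), m >= 2.
#' @param geom a [screen_geometry()].
#' @return precision in degrees.
#' @export
gaze_precision <- function(samples, geom) {
  samples <- as_points(samples)
  m <- nrow(samples)
  if (m < 2L) stop("precision needs at least 2 successive samples")
  th <- angular_separation(samples[-m, , drop = FALSE],
                           samples[-1, , drop = FALSE], geom)
  sqrt(mean(th^2))
}

#' Resample a gaze trace to a fixed number of uniform points
#'
#' Linear interpolation onto `n` uniformly spaced timestamps spanning the
#' trace; used to put predicted and target trajectories on the common
#' 180-point grid before computing pursuit RMSE.
#'
#' @param trace a [gaze_trace()].
#' @param n number of points (default 180).
#' @return a [gaze_trace()] with `n` rows.
#' @export
resample_trace <- function(trace, n = 180) {
  tt <- seq(trace$t_s[1], trace$t_s[nrow(trace)], length.out = n)
  gaze_trace(tt, stats::approx(trace$t_s, trace$x_mm, tt)$y,
             stats::approx(trace$t_s, trace$y_mm, tt)$y)
}

#' Pursuit trajectory RMSE
#'
#' Per-axis root mean square error between a predicted and a target gaze
#' trajectory sampled on the same grid (conventionally 180 points per
#' pursuit trial):
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum_i (pred_i - target_i)^2}}
#'
#' @param predicted,target [gaze_trace()]s (or data.frames with `x_mm`,
#'   `y_mm`) of equal length.
#' @return named numeric `c(rmse_x, rmse_y)` in mm.
#' @export
pursuit_rmse <- function(predicted, target) {
  if (nrow(predicted) != nrow(target))
    stop("predicted and target trajectories differ in length")
  c(rmse_x = sqrt(mean((predicted$x_mm - target$x_mm)^2)),
    rmse_y = sqrt(mean((predicted$y_mm - target$y_mm)^2)))
}

#' Convert between mm on screen and degrees of visual angle
#'
#' Helpers for distances measured from the screen center along the screen
#' plane.
#' @param d_mm distance in mm.
#' @param a_deg angle in degrees.
#' @param geom a [screen_geometry()].
#' @return converted value(s).
#' @export
mm_to_deg <- function(d_mm, geom) atan(d_mm / geom$distance) * 180 / pi

#' @rdname mm_to_deg
#' @export
deg_to_mm <- function(a_deg, geom) geom$distance * tan(a_deg * pi / 180)
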