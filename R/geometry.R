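#' Display geometry for angular velocity computation
#'
#' Describes the monitor the gaze was recorded on. Angular velocities depend
#' on the physical panel size and the viewing distance; gaze coordinates
#' themselves are normalized to `[0,1]^2` with origin at the top-left corner.
#' The default is a 24-inch 16:9 panel (531 x 299 mm) viewed from 650 mm,
#' matching a typical desktop eye-tracking setup.
#'
#' @param resolution integer vector `(width_px, height_px)`.
#' @param physical_width_mm,physical_height_mm panel size in millimetres.
#' @param viewing_distance_mm eye-to-screen distance in millimetres.
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(resolution = c(1920L, 1080L),
                             physical_width_mm = 531,
                             physical_height_mm = 299,
                             viewing_distance_mm = 650) {
  stopifnot(length(resolution) == 2, all(resolution > 0),
            physical_width_mm > 0, physical_height_mm > 0,
            viewing_distance_mm > 0)
  structure(list(resolution = as.integer(resolution),
                 physical_width_mm = physical_width_mm,
                 physical_height_mm = physical_height_mm,
                 viewing_distance_mm = viewing_distance_mm),
            class = "display_geometry")
}

## normalized [0,1] coords -> mm offsets from the screen centre (viewing axis)
.norm_to_mm <- function(xy, geom) {
  cbind((xy[, 1] - 0.5) * geom$physical_width_mm,
        (xy[, 2] - 0.5) * geom$physical_height_mm)
}

#' Visual angle between two on-screen points
#'
#' Angle subtended at the viewing position (on-axis, at
#' `viewing_distance_mm`) by two points given in normalized display
#' coordinates.
#'
#' @param p1,p2 numeric length-2 points, or n x 2 matrices (vectorized).
#' @param geom a [display_geometry()].
#' @return Angle(s) in degrees.
#' @export
visual_angle_deg <- function(p1, p2, geom) {
  p1 <- matrix(p1, ncol = 2)
  p2 <- matrix(p2, ncol = 2)
  m1 <- .norm_to_mm(p1, geom)
  m2 <- .norm_to_mm(p2, geom)
  d <- geom$viewing_distance_mm
  dot <- m1[, 1] * m2[, 1] + m1[, 2] * m2[, 2] + d * d
  n1 <- sqrt(m1[, 1]^2 + m1[, 2]^2 + d * d)
  n2 <- sqrt(m2[, 1]^2 + m2[, 2]^2 + d * d)
  acos(pmin(1, pmax(-1, dot / (n1 * n2)))) * 180 / pi
}

#' Angular gaze velocity between two samples
#'
#' @param p_prev,p_curr points in normalized coordinates.
#' @param dt_s time between the samples in seconds; must be positive.
#' @param geom a [display_geometry()].
#' @return Velocity in degrees per second (symmetric in the two points).
#' @export
angular_velocity <- function(p_prev, p_curr, dt_s, geom) {
  if (any(dt_s <= 0)) stop("dt_s must be positive")
  visual_angle_deg(p_prev, p_curr, geom) / dt_s
}
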