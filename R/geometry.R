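#' Eye and camera geometry
#'
#' Describes the physical eye (or model eye) and the camera that images it.
#' The defaults follow a standard artificial eyeball: a 5.5 mm pupil on a
#' 26 mm globe.  The camera model is orthographic: a rotation of the globe
#' by \eqn{\theta} about its centre displaces the projected pupil centre by
#' \eqn{p \cdot R \sin\theta} pixels, where \eqn{p} is `pixels_per_mm` and
#' \eqn{R = } `globe_diameter_mm / 2`.  The projection is invertible for
#' rotations up to 90 degrees and is used both by the frame simulator and
#' by [frames_to_trace()].
#'
#' `rest_x_px` / `rest_y_px` give the projected pupil centre at zero
#' rotation (the reference point from which angular displacement is
#' measured).  They default to a point left of the frame centre so that
#' temporal-ward (positive x) rotations up to 30 degrees stay inside the
#' frame.
#'
#' @param globe_diameter_mm Globe (eyeball) diameter in millimetres.
#' @param pupil_diameter_mm Pupil diameter in millimetres; must be smaller
#'   than the globe diameter.
#' @param pixels_per_mm Camera scale factor (pixels per millimetre at the
#'   plane of the pupil).
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param rest_x_px,rest_y_px Projected pupil centre at zero rotation, in
#'   the pixel coordinate frame (origin at the centre of the top-left
#'   pixel, x rightward, y downward).
#' @return An object of class `eye_geometry`.
#' @examples
#' geom <- eye_geometry()
#' angle_to_px(geom, 14)   # pixel displacement of a 14 degree rotation
#' px_to_angle(geom, angle_to_px(geom, 14))
#' @export
eye_geometry <- function(globe_diameter_mm = 26,
                         pupil_diameter_mm = 5.5,
                         pixels_per_mm = 6,
                         image_width_px = 128L,
                         image_height_px = 96L,
                         rest_x_px = 0.35 * image_width_px,
                         rest_y_px = 0.5 * (image_height_px - 1)) {
  stopifnot(
    is.numeric(globe_diameter_mm), globe_diameter_mm > 0,
    is.numeric(pupil_diameter_mm), pupil_diameter_mm > 0,
    pupil_diameter_mm < globe_diameter_mm,
    is.numeric(pixels_per_mm), pixels_per_mm > 0,
    image_width_px >= 16, image_height_px >= 16
  )
  g <- structure(
    list(
      globe_diameter_mm = globe_diameter_mm,
      pupil_diameter_mm = pupil_diameter_mm,
      pixels_per_mm     = pixels_per_mm,
      image_width_px    = as.integer(image_width_px),
      image_height_px   = as.integer(image_height_px),
      rest_x_px         = rest_x_px,
      rest_y_px         = rest_y_px
    ),
    class = "eye_geometry"
  )
  # the projected pupil must stay inside the frame for rotations <= 30 deg
  r_pupil <- pupil_radius_px(g)
  x_max <- rest_x_px + angle_to_px(g, 30) + r_pupil
  x_min <- rest_x_px - r_pupil
  if (x_min < 0 || x_max > image_width_px - 1 ||
      rest_y_px - r_pupil < 0 || rest_y_px + r_pupil > image_height_px - 1) {
    stop("projected pupil leaves the frame for rotations up to 30 degrees; ",
         "enlarge the image or reduce pixels_per_mm", call. = FALSE)
  }
  g
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf(
    "<eye_geometry> globe %.1f mm, pupil %.1f mm, %.2f px/mm, frame %dx%d px, rest (%.1f, %.1f)\n",
    x$globe_diameter_mm, x$pupil_diameter_mm, x$pixels_per_mm,
    x$image_width_px, x$image_height_px, x$rest_x_px, x$rest_y_px
  ))
  invisible(x)
}

pupil_radius_px <- function(geometry) {
  geometry$pixels_per_mm * geometry$pupil_diameter_mm / 2
}

globe_radius_px <- function(geometry) {
  geometry$pixels_per_mm * geometry$globe_diameter_mm / 2
}

#' Convert a rotation angle to a pixel displacement (and back)
#'
#' `angle_to_px()` maps a rotation of the globe (degrees) to the horizontal
#' displacement of the projected pupil centre (pixels) under the
#' orthographic camera model; `px_to_angle()` is its inverse.  Displacements
#' whose magnitude exceeds the globe radius have no preimage and map to
#' `NA` with a warning.
#'
#' @param geometry An [eye_geometry()].
#' @param angle_deg Rotation angle(s) in degrees.
#' @param dx_px Pixel displacement(s) from the resting position.
#' @return Numeric vector of displacements (pixels) or angles (degrees).
#' @export
angle_to_px <- function(geometry, angle_deg) {
  globe_radius_px(geometry) * sin(angle_deg * pi / 180)
}

#' @rdname angle_to_px
#' @export
px_to_angle <- function(geometry, dx_px) {
  s <- dx_px / globe_radius_px(geometry)
  out_of_domain <- is.finite(s) & abs(s) > 1
  if (any(out_of_domain)) {
    warning(sum(out_of_domain),
            " displacement(s) exceed the globe radius; returned as NA",
            call. = FALSE)
    s[out_of_domain] <- NA_real_
  }
  asin(s) * 180 / pi
}
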