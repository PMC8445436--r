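#' Device profiles
#'
#' A device profile carries the optical constants needed to map between
#' millimetres on a display and degrees of visual angle on the retina:
#' the viewing distance, a dimensionless angular scale (how many device
#' degrees one retinal degree spans), and the usable field of view.
#'
#' Two profiles are built in: `"perimeter"`, the stationary eye-tracking
#' perimeter used for diagnosis (400 mm viewing distance, scale 1.0), and
#' `"headset"`, the VR goggles used for training (44 mm to the phone screen,
#' scale 1.54, stereoscopic field of view of about 90 degrees). The registry
#' ships as plain JSON under `extdata/device_profiles.json`.
#'
#' @param name label for the profile.
#' @param viewing_distance_mm distance from the eye to the display, > 0.
#' @param angular_scale device degrees per retinal degree, > 0.
#' @param fov_deg full (diameter) field of view in device degrees, > 0.
#' @return An object of class `device_profile`.
#' @export
device_profile <- function(name, viewing_distance_mm, angular_scale = 1, fov_deg = 180) {
  if (!is.numeric(viewing_distance_mm) || length(viewing_distance_mm) != 1 ||
      !is.finite(viewing_distance_mm) || viewing_distance_mm <= 0) {
    stop("invalid device profile: viewing_distance_mm must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(angular_scale) || angular_scale <= 0) {
    stop("invalid device profile: angular_scale must be positive", call. = FALSE)
  }
  if (!is.numeric(fov_deg) || fov_deg <= 0) {
    stop("invalid device profile: fov_deg must be positive", call. = FALSE)
  }
  structure(
    list(name = as.character(name),
         viewing_distance_mm = as.numeric(viewing_distance_mm),
         angular_scale = as.numeric(angular_scale),
         fov_deg = as.numeric(fov_deg)),
    class = "device_profile"
  )
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf("<device_profile '%s': d = %g mm, scale = %g, fov = %g deg>\n",
              x$name, x$viewing_distance_mm, x$angular_scale, x$fov_deg))
  invisible(x)
}

#' @rdname device_profile
#' @details `device_profiles()` reads the bundled JSON registry and returns a
#'   named list of profiles; `perimeter_profile()` and `headset_profile()` are
#'   shorthands for its two built-in entries.
#' @export
device_profiles <- function() {
  path <- system.file("extdata", "device_profiles.json", package = "vftrain")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(raw, function(p) {
    device_profile(p$name, p$viewing_distance_mm, p$angular_scale, p$fov_deg)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname device_profile
#' @export
perimeter_profile <- function() device_profiles()[["perimeter"]]

#' @rdname device_profile
#' @export
headset_profile <- function() device_profiles()[["headset"]]

#' Convert a screen offset in millimetres to retinal degrees
#'
#' The angle subtended at the eye by an offset `s_mm` from screen centre at
#' viewing distance `distance_mm` is `2 * atan(s / (2 d))`, returned in
#' degrees. Odd and strictly increasing in `s_mm`, strictly decreasing in
#' `distance_mm` for positive offsets; for small offsets it approaches the
#' linear approximation `(180 / pi) * s / d`.
#'
#' @param s_mm signed offset from screen centre, millimetres (vectorised).
#' @param distance_mm viewing distance, millimetres, > 0.
#' @return Degrees of visual angle, same length as `s_mm`.
#' @export
screen_offset_to_retinal_deg <- function(s_mm, distance_mm) {
  if (!is.numeric(distance_mm) || length(distance_mm) != 1 ||
      !is.finite(distance_mm) || distance_mm <= 0) {
    stop("invalid device profile: viewing distance must be positive", call. = FALSE)
  }
  2 * atan(s_mm / (2 * distance_mm)) * 180 / pi
}

#' Inverse of [screen_offset_to_retinal_deg()]
#'
#' @param deg degrees of visual angle (vectorised).
#' @param distance_mm viewing distance, millimetres, > 0.
#' @return Offset from screen centre in millimetres.
#' @export
retinal_deg_to_screen_offset <- function(deg, distance_mm) {
  if (!is.numeric(distance_mm) || length(distance_mm) != 1 ||
      !is.finite(distance_mm) || distance_mm <= 0) {
    stop("invalid device profile: viewing distance must be positive", call. = FALSE)
  }
  2 * distance_mm * tan(deg * pi / 360)
}

#' Map a perimeter screen point to headset display degrees
#'
#' Each axis is converted independently: the millimetre offset on the
#' perimeter screen is turned into retinal degrees from the viewing distance
#' (400 mm for the built-in perimeter) and then multiplied by the headset's
#' angular scale (1.54 device degrees per retinal degree for the built-in
#' headset). A result outside the headset's half field of view raises an
#' out-of-field error carrying the clipped coordinate; callers that want
#' clamping catch the condition.
#'
#' @param p numeric length-2, `c(x_mm, y_mm)` offset from perimeter screen centre.
#' @param from source [device_profile()], default the built-in perimeter.
#' @param to target [device_profile()], default the built-in headset.
#' @return Numeric length-2 `c(x_deg, y_deg)` in target device degrees.
#' @export
perimeter_to_headset <- function(p, from = perimeter_profile(), to = headset_profile()) {
  stopifnot(is.numeric(p), length(p) == 2, all(is.finite(p)))
  deg <- screen_offset_to_retinal_deg(p, from$viewing_distance_mm) * to$angular_scale
  half <- to$fov_deg / 2
  if (any(abs(deg) > half)) {
    clipped <- pmin(pmax(deg, -half), half)
    cond <- structure(
      class = c("vftrain_out_of_field", "error", "condition"),
      list(message = sprintf(
             "converted position (%.3f, %.3f) deg lies outside the %s field of view (+/- %g deg)",
             deg[1], deg[2], to$name, half),
           call = sys.call(-1), position = deg, clipped = clipped)
    )
    stop(cond)
  }
  unname(deg)
}

#' Map headset display degrees back to a perimeter screen point
#'
#' Exact inverse of [perimeter_to_headset()] up to numeric tolerance.
#'
#' @param a numeric length-2, `c(x_deg, y_deg)` in headset device degrees.
#' @param from headset [device_profile()].
#' @param to perimeter [device_profile()].
#' @return Numeric length-2 `c(x_mm, y_mm)` on the perimeter screen.
#' @export
headset_to_perimeter <- function(a, from = headset_profile(), to = perimeter_profile()) {
  stopifnot(is.numeric(a), length(a) == 2, all(is.finite(a)))
  half <- from$fov_deg / 2
  if (any(abs(a) > half + 1e-9)) {
    stop(sprintf("position (%.3f, %.3f) deg is outside the %s field of view",
                 a[1], a[2], from$name), call. = FALSE)
  }
  unname(retinal_deg_to_screen_offset(a / from$angular_scale, to$viewing_distance_mm))
}

#' Euclidean distance between two angular positions
#'
#' Distances are taken in the flat two-dimensional degree plane, the standard
#' convention of static perimetry at eccentricities up to ~45 degrees; no
#' spherical correction is applied.
#'
#' @param a,b numeric length-2 positions in degrees.
#' @return Distance in degrees.
#' @export
angular_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 2, length(b) == 2)
  sqrt(sum((a - b)^2))
}
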