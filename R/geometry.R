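#' Screen geometry
#'
#' Describes the physical display used to convert pixel coordinates into
#' degrees of visual angle.  The angular origin is the screen centre;
#' x increases rightward and y increases downward, matching the
#' screen-pixel convention.
#'
#' @param width_px,height_px Display resolution in pixels.
#' @param width_mm,height_mm Physical display size in millimetres.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry(1920, 1080, 510, 287, 600)
#' px_to_deg(960 + 100, 540, geom)
#' @export
screen_geometry <- function(width_px, height_px, width_mm, height_mm,
                            viewing_distance_mm) {
  vals <- c(width_px, height_px, width_mm, height_mm, viewing_distance_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("screen geometry values must all be positive and finite")
  }
  aspect_px <- width_px / height_px
  aspect_mm <- width_mm / height_mm
  if (abs(aspect_px / aspect_mm - 1) > 0.05) {
    stop("pixel and physical aspect ratios disagree by more than 5%; ",
         "check width/height values")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         width_mm = width_mm, height_mm = height_mm,
         viewing_distance_mm = viewing_distance_mm),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.0f x %.0f mm, viewed at %.0f mm\n",
              x$width_px, x$height_px, x$width_mm, x$height_mm,
              x$viewing_distance_mm))
  invisible(x)
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Degrees are computed per axis as the arctangent of the physical offset
#' from screen centre over the viewing distance (no small-angle
#' approximation), so the conversion is exact at the eccentricities a
#' face-viewing paradigm uses and exactly invertible by [deg_to_px()].
#'
#' @param x_px,y_px Pixel coordinates (vectors of equal length).
#' @param geometry A [screen_geometry()].
#'
#' @return A data.frame with columns `x` and `y` in degrees; (0, 0) is the
#'   screen centre, x rightward and y downward positive.
#' @export
px_to_deg <- function(x_px, y_px, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  dx <- (x_px - geometry$width_px / 2) * mmx
  dy <- (y_px - geometry$height_px / 2) * mmy
  data.frame(
    x = atan(dx / geometry$viewing_distance_mm) * 180 / pi,
    y = atan(dy / geometry$viewing_distance_mm) * 180 / pi
  )
}

#' Convert degrees of visual angle back to pixel coordinates
#'
#' Exact inverse of [px_to_deg()].
#'
#' @param x_deg,y_deg Gaze angles in degrees relative to screen centre.
#' @param geometry A [screen_geometry()].
#' @return A data.frame with columns `x_px` and `y_px`.
#' @export
deg_to_px <- function(x_deg, y_deg, geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  mmx <- geometry$width_mm / geometry$width_px
  mmy <- geometry$height_mm / geometry$height_px
  d <- geometry$viewing_distance_mm
  data.frame(
    x_px = tan(x_deg * pi / 180) * d / mmx + geometry$width_px / 2,
    y_px = tan(y_deg * pi / 180) * d / mmy + geometry$height_px / 2
  )
}

#' Angular (great-arc) distance between gaze points
#'
#' Gaze angles (x, y) in degrees are mapped to 3-D gaze direction vectors
#' (tan x, tan y, 1) and the angle between the unit vectors is returned.
#' For the eccentricities used here (< 15 deg) this differs from the
#' planar Euclidean distance by well under 1%.
#'
#' @param x1,y1,x2,y2 Gaze angles in degrees (vectorised).
#' @return Angular distance in degrees.
#' @export
angular_distance <- function(x1, y1, x2, y2) {
  r <- pi / 180
  v1 <- cbind(tan(x1 * r), tan(y1 * r), 1)
  v2 <- cbind(tan(x2 * r), tan(y2 * r), 1)
  u1 <- v1 / sqrt(rowSums(v1^2))
  u2 <- v2 / sqrt(rowSums(v2^2))
  # half-angle (chord) form: exact at zero separation, stable for the
  # small angles gaze data live at
  chord <- sqrt(rowSums((u1 - u2)^2))
  2 * asin(pmin(1, chord / 2)) / r
}

#' Rectangular area of interest
#'
#' @param cx,cy Centre in degrees.
#' @param width,height Extent in degrees.
#' @return Named numeric vector `(x_min, x_max, y_min, y_max)`.
#' @export
aoi_rect <- function(cx, cy, width, height) {
  if (width <= 0 || height <= 0) stop("AOI width and height must be positive")
  c(x_min = cx - width / 2, x_max = cx + width / 2,
    y_min = cy - height / 2, y_max = cy + height / 2)
}

#' Eye and mouth areas of interest
#'
#' @param eyes,mouth Rectangles from [aoi_rect()] (or named vectors with
#'   `x_min`, `x_max`, `y_min`, `y_max`), in degrees.
#' @return An object of class `aoi_set`.
#' @export
aoi_set <- function(eyes, mouth) {
  check_rect <- function(r, nm) {
    need <- c("x_min", "x_max", "y_min", "y_max")
    if (!all(need %in% names(r))) stop(nm, " AOI must have x/y min/max")
    if (r["x_max"] <= r["x_min"] || r["y_max"] <= r["y_min"]) {
      stop(nm, " AOI rectangle is empty")
    }
    r[need]
  }
  eyes <- check_rect(eyes, "eyes")
  mouth <- check_rect(mouth, "mouth")
  overlap <- eyes["x_min"] < mouth["x_max"] && mouth["x_min"] < eyes["x_max"] &&
    eyes["y_min"] < mouth["y_max"] && mouth["y_min"] < eyes["y_max"]
  if (overlap) stop("eyes and mouth AOIs must not overlap")
  structure(list(eyes = eyes, mouth = mouth), class = "aoi_set")
}

#' Default AOI layout for a cued trial
#'
#' The stimulus is positioned so that the cued facial region is centred on
#' the fixation-cross location (the angular origin).  The eyes sit above
#' the mouth (y downward positive), with the AOI centres `separation`
#' degrees apart vertically.  The sizes are fixtures: the study this
#' emulates does not publish its AOI extents.
#'
#' @param condition `"eyes_cued"` or `"mouth_cued"`.
#' @param eyes_size,mouth_size Width/height in degrees.
#' @param separation Vertical distance between AOI centres, degrees.
#' @return An [aoi_set()].
#' @export
default_aoi_set <- function(condition = c("eyes_cued", "mouth_cued"),
                            eyes_size = c(8, 3), mouth_size = c(6, 2.5),
                            separation = 5) {
  condition <- match.arg(condition)
  if (condition == "eyes_cued") {
    eyes_c <- c(0, 0); mouth_c <- c(0, separation)
  } else {
    mouth_c <- c(0, 0); eyes_c <- c(0, -separation)
  }
  aoi_set(
    eyes = aoi_rect(eyes_c[1], eyes_c[2], eyes_size[1], eyes_size[2]),
    mouth = aoi_rect(mouth_c[1], mouth_c[2], mouth_size[1], mouth_size[2])
  )
}

#' Read/write AOI and screen geometry configuration (JSON)
#'
#' @param path Path to a JSON file.
#' @return `read_aoi_config()` returns a list with elements `aoi`
#'   (sizes/separation passed to [default_aoi_set()]) and, when present,
#'   `screen` (a [screen_geometry()]).
#' @export
read_aoi_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(cfg$aoi)) {
    out$aoi <- list(eyes_size = as.numeric(cfg$aoi$eyes_size),
                    mouth_size = as.numeric(cfg$aoi$mouth_size),
                    separation = as.numeric(cfg$aoi$separation))
  }
  if (!is.null(cfg$screen)) {
    out$screen <- do.call(screen_geometry, as.list(cfg$screen))
  }
  out
}

#' @rdname read_aoi_config
#' @param config List as returned by `read_aoi_config()`; the `screen`
#'   element may be a `screen_geometry`.
#' @export
write_aoi_config <- function(config, path) {
  if (inherits(config$screen, "screen_geometry")) {
    config$screen <- unclass(config$screen)
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
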