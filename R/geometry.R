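#' Display geometry
#'
#' Describes the screen the stimuli were shown on: its resolution in pixels
#' and its angular extent in degrees of visual angle. All conversions between
#' angular quantities (kernel widths, disc radii) and the pixel grid go
#' through this object. The conversion is linear per axis (small-angle
#' approximation); a single global extent is assumed, not a per-pixel tangent
#' correction.
#'
#' @param width_px,height_px Screen resolution in pixels (integers >= 1).
#' @param width_deg,height_deg Stimulus extent in degrees of visual angle
#'   (> 0).
#'
#' @return An object of class `display_geometry`: a list with the four
#'   fields plus derived `px_per_deg_x` and `px_per_deg_y`.
#'
#' @examples
#' geom <- display_geometry(1280, 960, 28.4, 21.3)
#' deg_to_px(geom, 2, "x") # about 90.1 px
#' @export
display_geometry <- function(width_px, height_px, width_deg, height_deg) {
  stopifnot(
    is.numeric(width_px), is.numeric(height_px),
    is.numeric(width_deg), is.numeric(height_deg),
    length(width_px) == 1, length(height_px) == 1,
    length(width_deg) == 1, length(height_deg) == 1
  )
  if (width_px < 1 || height_px < 1 || width_px != round(width_px) ||
      height_px != round(height_px)) {
    stop("width_px and height_px must be integers >= 1", call. = FALSE)
  }
  if (!is.finite(width_deg) || !is.finite(height_deg) ||
      width_deg <= 0 || height_deg <= 0) {
    stop("width_deg and height_deg must be finite and > 0", call. = FALSE)
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      width_deg = width_deg, height_deg = height_deg,
      px_per_deg_x = width_px / width_deg,
      px_per_deg_y = height_px / height_deg
    ),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "<display_geometry> %d x %d px, %.4g x %.4g deg (%.3f / %.3f px per deg)\n",
    x$width_px, x$height_px, x$width_deg, x$height_deg,
    x$px_per_deg_x, x$px_per_deg_y
  ))
  invisible(x)
}

#' Convert degrees of visual angle to pixels
#'
#' Linear per-axis conversion `d * px_per_deg`. Exact for the small angles
#' typical of screen-based eye tracking.
#'
#' @param geometry A [display_geometry()].
#' @param d Angular distance in degrees, `>= 0` (vectorised).
#' @param axis `"x"` or `"y"`; the axes may have different pixel densities.
#' @return Distance in pixels.
#' @export
deg_to_px <- function(geometry, d, axis = c("x", "y")) {
  stopifnot(inherits(geometry, "display_geometry"), is.numeric(d))
  axis <- match.arg(axis)
  if (any(d < 0)) stop("angular distance must be >= 0", call. = FALSE)
  d * if (axis == "x") geometry$px_per_deg_x else geometry$px_per_deg_y
}

#' Convert pixels to degrees of visual angle
#' @inheritParams deg_to_px
#' @param p Distance in pixels, `>= 0` (vectorised).
#' @return Distance in degrees.
#' @export
px_to_deg <- function(geometry, p, axis = c("x", "y")) {
  stopifnot(inherits(geometry, "display_geometry"), is.numeric(p))
  axis <- match.arg(axis)
  if (any(p < 0)) stop("pixel distance must be >= 0", call. = FALSE)
  p / if (axis == "x") geometry$px_per_deg_x else geometry$px_per_deg_y
}

#' Read or write a display geometry as JSON/YAML
#'
#' The on-disk form is a mapping with keys `width_px`, `height_px`,
#' `width_deg`, `height_deg`. The format is chosen by file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path File to read from / write to.
#' @return `read_geometry()` returns a [display_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path, call. = FALSE)
  g <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("width_px", "height_px", "width_deg", "height_deg")
  if (!all(need %in% names(g))) {
    stop("geometry file must define ", paste(need, collapse = ", "), call. = FALSE)
  }
  display_geometry(g$width_px, g$height_px, g$width_deg, g$height_deg)
}

#' @rdname read_geometry
#' @param geometry A [display_geometry()].
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "display_geometry"))
  g <- geometry[c("width_px", "height_px", "width_deg", "height_deg")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(g, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(g, path)
  }
  invisible(path)
}
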