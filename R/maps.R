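#' Salience and fixation-density maps
#'
#' A salience map is a 2-D grid of finite real values covering the screen,
#' stored as a numeric matrix (rows = y, cols = x) with the display geometry
#' and a `scale` attribute: grid cells per screen pixel (`<= 1`), so a
#' 320 x 240 map on a 1280 x 960 screen has scale 1/4. A density map is a
#' salience map that is additionally non-negative and sums to one ("unit
#' mass"); it represents a fixation probability distribution over grid
#' cells.
#'
#' @param values Numeric matrix, rows x cols.
#' @param geometry A [display_geometry()].
#' @param scale Grid cells per screen pixel. If `NULL`, inferred from the
#'   matrix shape; the screen dimensions must be integer multiples of the
#'   grid dimensions, and both axes must share the same factor.
#' @return A matrix of class `salience_map` (or `density_map`) with
#'   attributes `geometry` and `scale`.
#' @export
salience_map <- function(values, geometry, scale = NULL) {
  stopifnot(is.matrix(values), is.numeric(values),
            inherits(geometry, "display_geometry"))
  if (!all(is.finite(values))) stop("map values must all be finite", call. = FALSE)
  scale <- check_map_shape(dim(values), geometry, scale)
  structure(values,
    geometry = geometry, scale = scale,
    class = c("salience_map", class(values))
  )
}

#' @rdname salience_map
#' @param tol Tolerance on the unit-mass check.
#' @export
density_map <- function(values, geometry, scale = NULL, tol = 1e-9) {
  m <- salience_map(values, geometry, scale)
  if (any(m < 0)) stop("density map values must be >= 0", call. = FALSE)
  if (abs(sum(m) - 1) > tol) {
    stop("density map must sum to 1 (got ", format(sum(m)), ")", call. = FALSE)
  }
  class(m) <- c("density_map", class(m))
  m
}

#' @rdname salience_map
#' @details `as_density_map()` normalizes a non-negative map to unit mass.
#' @param map A `salience_map` or plain matrix.
#' @export
as_density_map <- function(map, geometry = NULL, scale = NULL) {
  if (inherits(map, "salience_map")) {
    geometry <- map_geometry(map)
    scale <- map_scale(map)
  }
  v <- unclass_map(map)
  if (any(v < 0)) stop("cannot normalize a map with negative values", call. = FALSE)
  s <- sum(v)
  if (s <= 0) stop("cannot normalize a zero map", call. = FALSE)
  density_map(v / s, geometry, scale)
}

check_map_shape <- function(shape, geometry, scale) {
  rows <- shape[1]; cols <- shape[2]
  if (is.null(scale)) {
    if (geometry$width_px %% cols != 0 || geometry$height_px %% rows != 0) {
      stop("map shape ", rows, " x ", cols,
           " is not an integer divisor of the screen shape ",
           geometry$height_px, " x ", geometry$width_px, call. = FALSE)
    }
    fx <- geometry$width_px %/% cols
    fy <- geometry$height_px %/% rows
    if (fx != fy) {
      stop("map shape implies different scales per axis (1/", fy, " vs 1/",
           fx, ")", call. = FALSE)
    }
    scale <- 1 / fx
  } else {
    if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
    if (abs(cols - geometry$width_px * scale) > 0.5 ||
        abs(rows - geometry$height_px * scale) > 0.5) {
      stop("map shape inconsistent with geometry x scale", call. = FALSE)
    }
  }
  scale
}

#' @export
print.salience_map <- function(x, ...) {
  g <- map_geometry(x)
  cat(sprintf(
    "<%s> %d x %d cells (scale %.4g) on %d x %d px; range [%.4g, %.4g], sum %.6g\n",
    class(x)[1], nrow(x), ncol(x), map_scale(x), g$width_px, g$height_px,
    min(x), max(x), sum(x)
  ))
  invisible(x)
}

#' Map attribute accessors
#' @param map A `salience_map` or `density_map`.
#' @return The attached [display_geometry()] / the scale (cells per pixel) /
#'   the bare numeric matrix.
#' @export
map_geometry <- function(map) {
  g <- attr(map, "geometry", exact = TRUE)
  if (is.null(g)) stop("map carries no display geometry", call. = FALSE)
  g
}

#' @rdname map_geometry
#' @export
map_scale <- function(map) {
  s <- attr(map, "scale", exact = TRUE)
  if (is.null(s)) stop("map carries no scale attribute", call. = FALSE)
  s
}

unclass_map <- function(map) {
  v <- as.matrix(map)
  attr(v, "geometry") <- NULL
  attr(v, "scale") <- NULL
  class(v) <- setdiff(class(v), c("density_map", "salience_map"))
  v
}

#' Grid cell indices of fixation positions
#'
#' Maps pixel coordinates onto the cells of a map's grid (nearest containing
#' cell, no interpolation). With grid scale `s` a fixation at pixel `(x, y)`
#' falls into column `floor(x * s) + 1` and row `floor(y * s) + 1`.
#'
#' @param map A `salience_map`.
#' @param x,y Pixel coordinates within the screen bounds.
#' @return A list with integer vectors `row`, `col` and the linear
#'   (column-major) index `idx`.
#' @export
map_cell_index <- function(map, x, y) {
  g <- map_geometry(map)
  s <- map_scale(map)
  if (any(x < 0 | x >= g$width_px | y < 0 | y >= g$height_px)) {
    stop("fixation positions outside the screen", call. = FALSE)
  }
  col <- pmin(floor(x * s) + 1L, ncol(map))
  row <- pmin(floor(y * s) + 1L, nrow(map))
  list(row = as.integer(row), col = as.integer(col),
       idx = as.integer((col - 1L) * nrow(map) + row))
}

#' Read and write 2-D maps
#'
#' Plain-text maps are whitespace-delimited matrices, one grid row per line.
#' Grayscale rasters (PNG or TIFF, 8/16 bit) are read with their stored
#' intensities as real values. The grid scale is inferred from the shape
#' relative to the geometry.
#'
#' @param path File path. `.png` and `.tif`/`.tiff` are treated as rasters,
#'   anything else as a text matrix.
#' @param geometry A [display_geometry()].
#' @return `read_map()` returns a `salience_map`; `write_map()` returns
#'   `path` invisibly (text matrix output).
#' @export
read_map <- function(path, geometry) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- png::readPNG(path)
    v <- collapse_raster(v)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- tiff::readTIFF(path)
    v <- collapse_raster(v)
  } else {
    rows <- readLines(path, warn = FALSE)
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) == 0) stop("empty map file: ", path, call. = FALSE)
    parsed <- lapply(strsplit(trimws(rows), "[[:space:]]+"), as.numeric)
    lens <- lengths(parsed)
    if (length(unique(lens)) != 1) {
      stop("ragged rows in text map: ", path, call. = FALSE)
    }
    if (anyNA(unlist(parsed))) {
      stop("non-numeric entries in text map: ", path, call. = FALSE)
    }
    v <- do.call(rbind, parsed)
  }
  salience_map(v, geometry)
}

collapse_raster <- function(v) {
  if (length(dim(v)) == 3) {
    if (dim(v)[3] >= 3) v <- v[, , 1:3, drop = FALSE] else v <- v[, , 1, drop = FALSE]
    v <- apply(v, c(1, 2), mean)
  }
  v
}

#' @rdname read_map
#' @param map A `salience_map` or `density_map`.
#' @param digits Significant digits written for each value.
#' @export
write_map <- function(map, path, digits = 17) {
  v <- unclass_map(map)
  lines <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
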