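#' Smoothing specification for fixation density maps
#'
#' Fixation density maps are smoothed with a Gaussian kernel whose width is
#' given as full width at half maximum (FWHM) in degrees of visual angle.
#' The default of 2 degrees reflects eye-tracker calibration error and the
#' ~2 degree diameter of the fovea. The FWHM is converted per axis to a
#' standard deviation in grid cells, `sigma = FWHM / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm_deg Kernel full width at half maximum in degrees (> 0).
#' @param kernel Kernel family; only `"gaussian"` is implemented.
#' @return A `smoothing_spec` object.
#' @export
smoothing_spec <- function(fwhm_deg = 2, kernel = "gaussian") {
  stopifnot(is.numeric(fwhm_deg), length(fwhm_deg) == 1)
  if (!is.finite(fwhm_deg) || fwhm_deg <= 0) {
    stop("fwhm_deg must be finite and > 0", call. = FALSE)
  }
  kernel <- match.arg(kernel, "gaussian")
  structure(list(fwhm_deg = fwhm_deg, kernel = kernel),
            class = "smoothing_spec")
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Two-dimensional fixation histogram
#'
#' Counts fixations into a `rows x cols` grid of equal half-open cells
#' partitioning the screen `[0, W) x [0, H)`. The total count equals the
#' number of fixations.
#'
#' @param fixations A `fixation_df` (or data frame with `x`, `y`) within
#'   screen bounds.
#' @param grid Integer vector `c(rows, cols)`; both must divide the screen
#'   dimensions is not required, cells are `W/cols` by `H/rows` pixels.
#' @param geometry Display geometry; defaults to the one attached to
#'   `fixations`.
#' @return An integer count matrix with attributes `geometry` and `scale`
#'   when the grid is an isotropic rescaling of the screen.
#' @export
fixation_histogram <- function(fixations, grid, geometry = fx_geometry(fixations)) {
  stopifnot(length(grid) == 2, all(grid >= 1), all(grid == round(grid)))
  rows <- as.integer(grid[1]); cols <- as.integer(grid[2])
  x <- fixations$x; y <- fixations$y
  if (length(x) == 0) {
    h <- matrix(0L, rows, cols)
    attr(h, "empty") <- TRUE
    return(h)
  }
  if (any(x < 0 | x >= geometry$width_px | y < 0 | y >= geometry$height_px)) {
    stop("fixations outside the screen bounds", call. = FALSE)
  }
  col <- pmin(floor(x * cols / geometry$width_px) + 1L, cols)
  row <- pmin(floor(y * rows / geometry$height_px) + 1L, rows)
  idx <- (col - 1L) * rows + row
  h <- matrix(tabulate(idx, nbins = rows * cols), rows, cols)
  h
}

# Separable truncated-Gaussian smoothing. sigma in grid cells per axis;
# kernels are cut at 4 sigma and NOT renormalized at the borders -- mass
# leaking off the screen is recovered by the global unit-mass normalization
# of the caller, which keeps interior values unchanged.
smooth_gaussian <- function(values, sigma_row, sigma_col, truncate = 4) {
  out <- values
  if (sigma_row > 1e-6) {
    out <- smoothing_matrix(nrow(out), sigma_row, truncate) %*% out
  }
  if (sigma_col > 1e-6) {
    out <- out %*% smoothing_matrix(ncol(out), sigma_col, truncate)
  }
  out
}

smoothing_matrix <- function(n, sigma, truncate = 4) {
  r <- min(n - 1, ceiling(truncate * sigma))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k[abs(d) > r] <- 0
  # column-normalized so each source cell spreads (at most) unit mass
  sweep(k, 2, dnorm_sum(sigma, r), "/")
}

dnorm_sum <- function(sigma, r) {
  sum(exp(-((-r):r)^2 / (2 * sigma^2)))
}

#' Fixation density map
#'
#' Estimates the probability that each grid cell is fixated by smoothing a
#' two-dimensional fixation histogram (one bin per grid cell) with a
#' Gaussian kernel and normalizing the result to unit mass. The kernel
#' standard deviation is computed per axis from the angular FWHM and the
#' pixel density, scaled to the working grid.
#'
#' @param fixations A `fixation_df` selection with at least one fixation.
#' @param smoothing A [smoothing_spec()].
#' @param scale Working grid scale: cells per screen pixel (`<= 1`). The
#'   screen dimensions times `scale` must be (near-)integers.
#' @param geometry Display geometry; defaults to the attached one.
#' @return A `density_map` on the `scale` grid.
#' @export
fdm <- function(fixations, smoothing = smoothing_spec(), scale = 1,
                geometry = fx_geometry(fixations)) {
  if (nrow(fixations) == 0) {
    stop("cannot estimate a fixation density map from zero fixations",
         call. = FALSE)
  }
  rows <- round(geometry$height_px * scale)
  cols <- round(geometry$width_px * scale)
  h <- fixation_histogram(fixations, c(rows, cols), geometry)
  sigma_col <- deg_to_px(geometry, smoothing$fwhm_deg, "x") * scale * FWHM_TO_SIGMA
  sigma_row <- deg_to_px(geometry, smoothing$fwhm_deg, "y") * scale * FWHM_TO_SIGMA
  sm <- smooth_gaussian(h, sigma_row, sigma_col)
  sm[sm < 0] <- 0 # numerical noise from the matrix products
  density_map(sm / sum(sm), geometry, scale = scale)
}

#' Downsample a density map by block summation
#'
#' Aggregates `factor x factor` blocks of cells by summation, so unit mass
#' (and counts, when applied to histograms) are conserved exactly. No
#' interpolation is performed.
#'
#' @param map A `density_map`.
#' @param factor Integer >= 1 dividing both grid dimensions.
#' @return A `density_map` at scale `map_scale(map) / factor`.
#' @export
downsample <- function(map, factor) {
  stopifnot(length(factor) == 1, factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(map)
  if (nrow(map) %% factor != 0 || ncol(map) %% factor != 0) {
    stop("factor ", factor, " does not divide the grid dimensions ",
         nrow(map), " x ", ncol(map), call. = FALSE)
  }
  v <- unclass_map(map)
  v <- block_sum(v, factor)
  density_map(v, map_geometry(map), scale = map_scale(map) / factor)
}

block_sum <- function(v, factor) {
  r2 <- nrow(v) %/% factor; c2 <- ncol(v) %/% factor
  dim(v) <- c(factor, r2, factor, c2)
  colSums(aperm(v, c(1, 3, 2, 4)), dims = 2)
}

#' Spatial (central) bias of a fixation dataset
#'
#' The image- and subject-independent distribution of fixation locations:
#' the FDM over all fixations of the selected subjects on the selected
#' images, pooled. Typically computed per stimulus category.
#'
#' @param fixations A `fixation_df`.
#' @param subjects,images Optional identifier vectors restricting the pool;
#'   `NULL` keeps everything.
#' @inheritParams fdm
#' @return A `density_map`.
#' @export
spatial_bias <- function(fixations, subjects = NULL, images = NULL,
                         smoothing = smoothing_spec(), scale = 1) {
  g <- fx_geometry(fixations)
  sel <- tibble::as_tibble(fixations)
  if (!is.null(subjects)) sel <- dplyr::filter(sel, .data$subject %in% !!subjects)
  if (!is.null(images)) sel <- dplyr::filter(sel, .data$image %in% !!images)
  if (nrow(sel) == 0) {
    stop("no fixations in the selected subject/image intersection", call. = FALSE)
  }
  fdm(sel, smoothing = smoothing, scale = scale, geometry = g)
}
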