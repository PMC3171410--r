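#' Configuration for the synthetic fixation generator
#'
#' The generator emulates the structure of free-viewing eye-tracking
#' datasets: a category-dependent central (spatial) bias, image-specific
#' fixation hotspots shared across subjects, and stable subject-specific
#' spatial-bias components. Every fixation is drawn from a three-component
#' mixture: with probability `w_central` from the category's central-bias
#' Gaussian, with `w_hotspot` from a uniformly chosen hotspot Gaussian of
#' the trial's image (hotspot centres drawn once per image and shared by
#' all subjects), and with `w_subject` from the subject's idiosyncratic
#' Gaussian -- the central-bias Gaussian shifted by a subject offset that
#' is a linear combination of `n_subject_components` fixed 2-D component
#' directions with per-subject weights `~ Normal(0, subject_weight_sd)`.
#' Samples are truncated to the screen by rejection, so every component
#' density is a properly renormalized truncated Gaussian.
#'
#' @param n_subjects,n_images Counts (>= 1). Images are split evenly over
#'   the categories.
#' @param fixations_per_trial Fixations per (subject, image) trial
#'   (default 15).
#' @param categories Named list; each entry has `center` (2-vector, screen
#'   fractions) and `sd_deg` (2-vector, per-axis SD in degrees). The
#'   defaults mimic a tight central bias for outdoor "naturals" and a more
#'   spread-out bias for "urbans".
#' @param hotspots_per_image Hotspots per image.
#' @param hotspot_sd_deg SD of each hotspot Gaussian in degrees.
#' @param mixture_weights Numeric 3-vector `(w_central, w_hotspot,
#'   w_subject)`, non-negative, summing to 1.
#' @param n_subject_components Number of planted subject-bias directions.
#' @param subject_weight_sd SD (degrees) of the per-subject component
#'   weights.
#' @param geometry Display geometry; defaults to a 1280 x 960 px screen
#'   spanning 28.4 x 21.3 degrees.
#' @param seed Root seed; independent per-stream generators are derived
#'   from it so e.g. changing `n_subjects` does not reshuffle the image
#'   layouts.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects, n_images, fixations_per_trial = 15,
                             categories = list(
                               naturals = list(center = c(0.5, 0.5), sd_deg = c(4.5, 3.5)),
                               urbans = list(center = c(0.5, 0.5), sd_deg = c(8, 6))
                             ),
                             hotspots_per_image = 2, hotspot_sd_deg = 1.5,
                             mixture_weights = c(0.45, 0.4, 0.15),
                             n_subject_components = 2, subject_weight_sd = 1.5,
                             geometry = display_geometry(1280, 960, 28.4, 21.3),
                             seed = 1) {
  stopifnot(n_subjects >= 1, n_images >= 1, fixations_per_trial >= 1,
            hotspots_per_image >= 1, n_subject_components >= 1)
  if (length(mixture_weights) != 3 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-9) {
    stop("mixture_weights must be 3 non-negative numbers summing to 1",
         call. = FALSE)
  }
  if (hotspot_sd_deg <= 0 || subject_weight_sd < 0) {
    stop("component SDs must be positive", call. = FALSE)
  }
  for (cat in categories) {
    if (any(cat$sd_deg <= 0)) stop("category sd_deg must be > 0", call. = FALSE)
  }
  structure(list(
    n_subjects = n_subjects, n_images = n_images,
    fixations_per_trial = fixations_per_trial,
    categories = categories,
    hotspots_per_image = hotspots_per_image, hotspot_sd_deg = hotspot_sd_deg,
    mixture_weights = mixture_weights,
    n_subject_components = n_subject_components,
    subject_weight_sd = subject_weight_sd,
    geometry = geometry, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic fixation dataset with known ground truth
#'
#' Draws the full `n_subjects x n_images x fixations_per_trial` dataset
#' from the mixture described in [synthetic_config()]. The returned
#' `truth` bundle records the image layouts (hotspot centres), the planted
#' subject-bias components and per-subject offsets, and the configuration,
#' so every component density can be evaluated analytically with
#' [ground_truth_density()].
#'
#' @param config A [synthetic_config()].
#' @return A list with `fixations` (a `fixation_df`) and `truth` (a
#'   `synthetic_truth` bundle).
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$geometry
  cats <- names(config$categories)

  # stream 1: image layout (category assignment round-robin + hotspots,
  # uniform over the central 80% of the screen to keep border truncation
  # from dominating coarse grids)
  set.seed(config$seed * 3L + 1L)
  image_ids <- sprintf("img%03d", seq_len(config$n_images))
  image_cat <- cats[((seq_len(config$n_images) - 1L) %% length(cats)) + 1L]
  hotspots <- lapply(seq_len(config$n_images), function(i) {
    cbind(
      x = stats::runif(config$hotspots_per_image, 0.1 * g$width_px, 0.9 * g$width_px),
      y = stats::runif(config$hotspots_per_image, 0.1 * g$height_px, 0.9 * g$height_px)
    )
  })

  # stream 2: subject components and weights
  set.seed(config$seed * 3L + 2L)
  comp_dirs <- matrix(stats::rnorm(2 * config$n_subject_components),
                      ncol = 2) # rows: components; cols: x,y (degrees)
  comp_dirs <- comp_dirs / sqrt(rowSums(comp_dirs^2))
  subj_w <- matrix(stats::rnorm(config$n_subjects * config$n_subject_components,
                                sd = config$subject_weight_sd),
                   nrow = config$n_subjects)
  offsets_deg <- subj_w %*% comp_dirs # per-subject offset in degrees
  offsets_px <- cbind(offsets_deg[, 1] * g$px_per_deg_x,
                      offsets_deg[, 2] * g$px_per_deg_y)
  subject_ids <- sprintf("s%02d", seq_len(config$n_subjects))

  # stream 3: fixation draws
  set.seed(config$seed * 3L + 3L)
  trials <- tidyr::expand_grid(
    subject_i = seq_len(config$n_subjects),
    image_i = seq_len(config$n_images)
  )
  per <- config$fixations_per_trial
  n_fix <- nrow(trials) * per
  fx <- tibble::tibble(
    subject_i = rep(trials$subject_i, each = per),
    image_i = rep(trials$image_i, each = per),
    trial_index = rep(seq_len(per), times = nrow(trials))
  )
  comp <- sample.int(3L, n_fix, replace = TRUE, prob = config$mixture_weights)

  cat_of <- image_cat[fx$image_i]
  mu_x <- numeric(n_fix); mu_y <- numeric(n_fix)
  sd_x <- numeric(n_fix); sd_y <- numeric(n_fix)
  for (cn in cats) {
    cc <- config$categories[[cn]]
    sel <- cat_of == cn
    mu_x[sel] <- cc$center[1] * g$width_px
    mu_y[sel] <- cc$center[2] * g$height_px
    sd_x[sel] <- cc$sd_deg[1] * g$px_per_deg_x
    sd_y[sel] <- cc$sd_deg[2] * g$px_per_deg_y
  }
  # hotspot component: pick one hotspot of the trial's image per fixation
  hs <- comp == 2L
  if (any(hs)) {
    hot_x <- do.call(rbind, lapply(hotspots, function(h) h[, "x"]))
    hot_y <- do.call(rbind, lapply(hotspots, function(h) h[, "y"]))
    pick <- sample.int(config$hotspots_per_image, sum(hs), replace = TRUE)
    mu_x[hs] <- hot_x[cbind(fx$image_i[hs], pick)]
    mu_y[hs] <- hot_y[cbind(fx$image_i[hs], pick)]
    sd_x[hs] <- config$hotspot_sd_deg * g$px_per_deg_x
    sd_y[hs] <- config$hotspot_sd_deg * g$px_per_deg_y
  }
  # subject component: shift the category Gaussian by the subject's offset
  sj <- comp == 3L
  if (any(sj)) {
    mu_x[sj] <- mu_x[sj] + offsets_px[fx$subject_i[sj], 1]
    mu_y[sj] <- mu_y[sj] + offsets_px[fx$subject_i[sj], 2]
  }

  # truncated-Gaussian draw by rejection against the screen box
  x <- stats::rnorm(n_fix, mu_x, sd_x)
  y <- stats::rnorm(n_fix, mu_y, sd_y)
  bad <- x < 0 | x >= g$width_px | y < 0 | y >= g$height_px
  guard <- 0L
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mu_x[bad], sd_x[bad])
    y[bad] <- stats::rnorm(sum(bad), mu_y[bad], sd_y[bad])
    bad <- x < 0 | x >= g$width_px | y < 0 | y >= g$height_px
    guard <- guard + 1L
    if (guard > 10000L) stop("rejection sampling failed to converge", call. = FALSE)
  }

  fixations <- fixation_data(
    tibble::tibble(
      subject = subject_ids[fx$subject_i],
      image = image_ids[fx$image_i],
      category = cat_of,
      trial_index = fx$trial_index,
      x = x, y = y
    ),
    g, max_fixations = per
  )

  truth <- structure(list(
    config = config, geometry = g,
    images = tibble::tibble(image = image_ids, category = image_cat,
                            hotspots = hotspots),
    subjects = tibble::tibble(subject = subject_ids,
                              offset_x_px = offsets_px[, 1],
                              offset_y_px = offsets_px[, 2]),
    component_dirs = comp_dirs, subject_weights = subj_w
  ), class = "synthetic_truth")

  list(fixations = fixations, truth = truth)
}

#' Truncated-Gaussian cell probabilities on a grid
#'
#' Discretizes an axis-aligned 2-D Gaussian, truncated to the screen, on a
#' `rows x cols` grid: the product of the two 1-D truncated marginals,
#' renormalized to unit mass. The analytic building block of every
#' synthetic ground-truth density; also handy as a smooth test density for
#' the entropy simulations.
#'
#' @param geometry A [display_geometry()].
#' @param grid `c(rows, cols)`.
#' @param mu Mean `c(x, y)` in pixels.
#' @param sd SD `c(x, y)` in pixels.
#' @return A unit-mass matrix (rows x cols).
#' @export
truncated_gauss_grid <- function(geometry, grid, mu, sd) {
  rows <- grid[1]; cols <- grid[2]
  ex <- seq(0, geometry$width_px, length.out = cols + 1)
  ey <- seq(0, geometry$height_px, length.out = rows + 1)
  px <- diff(stats::pnorm(ex, mu[1], sd[1]))
  py <- diff(stats::pnorm(ey, mu[2], sd[2]))
  m <- outer(py, px)
  m / sum(m)
}

#' Analytic ground-truth density of a synthetic dataset
#'
#' Evaluates the exact mixture density the generator sampled from,
#' discretized on a grid: per-component truncated Gaussians combined with
#' the configured mixture weights. For `subject = NULL` the subject
#' component is averaged ("pooled") over all subjects; for `image = NULL`
#' the hotspot component is averaged over all images of the requested
#' pool.
#'
#' @param truth A `synthetic_truth` bundle from [make_dataset()].
#' @param image Image id, or `NULL` to pool over images.
#' @param subject Subject id, or `NULL` to pool over subjects.
#' @param grid `c(rows, cols)` of the evaluation grid.
#' @return A `density_map`.
#' @export
ground_truth_density <- function(truth, image = NULL, subject = NULL,
                                 grid = coarse_grid(truth$geometry)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- truth$config
  g <- truth$geometry
  imgs <- truth$images
  if (!is.null(image)) {
    if (!image %in% imgs$image) stop("unknown image id: ", image, call. = FALSE)
    imgs <- imgs[imgs$image == image, ]
  }
  if (!is.null(subject) && !subject %in% truth$subjects$subject) {
    stop("unknown subject id: ", subject, call. = FALSE)
  }
  w <- cfg$mixture_weights

  # central component: average the per-category bias over the image pool
  central <- 0
  for (i in seq_len(nrow(imgs))) {
    cc <- cfg$categories[[imgs$category[i]]]
    central <- central + truncated_gauss_grid(
      g, grid,
      mu = c(cc$center[1] * g$width_px, cc$center[2] * g$height_px),
      sd = c(cc$sd_deg[1] * g$px_per_deg_x, cc$sd_deg[2] * g$px_per_deg_y)
    )
  }
  central <- central / nrow(imgs)

  hotspot <- 0
  hsd <- c(cfg$hotspot_sd_deg * g$px_per_deg_x, cfg$hotspot_sd_deg * g$px_per_deg_y)
  for (i in seq_len(nrow(imgs))) {
    hcent <- imgs$hotspots[[i]]
    per_img <- 0
    for (k in seq_len(nrow(hcent))) {
      per_img <- per_img + truncated_gauss_grid(g, grid, hcent[k, ], hsd)
    }
    hotspot <- hotspot + per_img / nrow(hcent)
  }
  hotspot <- hotspot / nrow(imgs)

  subj_pool <- if (is.null(subject)) truth$subjects else
    truth$subjects[truth$subjects$subject == subject, ]
  subj_comp <- 0
  for (i in seq_len(nrow(imgs))) {
    cc <- cfg$categories[[imgs$category[i]]]
    sdv <- c(cc$sd_deg[1] * g$px_per_deg_x, cc$sd_deg[2] * g$px_per_deg_y)
    base_mu <- c(cc$center[1] * g$width_px, cc$center[2] * g$height_px)
    per_img <- 0
    for (s in seq_len(nrow(subj_pool))) {
      per_img <- per_img + truncated_gauss_grid(
        g, grid,
        mu = base_mu + c(subj_pool$offset_x_px[s], subj_pool$offset_y_px[s]),
        sd = sdv
      )
    }
    subj_comp <- subj_comp + per_img / nrow(subj_pool)
  }
  subj_comp <- subj_comp / nrow(imgs)

  mix <- w[1] * central + w[2] * hotspot + w[3] * subj_comp
  density_map(mix / sum(mix), g, scale = grid[2] / g$width_px)
}
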