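# Small shared fixtures, all built in code.

paper_geom <- function() display_geometry(1280, 960, 28.4, 21.3)

# a small screen with 2 px per degree on both axes
tiny_geom <- function() display_geometry(64, 48, 32, 24)

fix_df <- function(geom, x, y, subject = "s1", image = "i1",
                   category = "free", trial_index = seq_along(x),
                   max_fixations = Inf) {
  fixation_data(
    tibble::tibble(subject = subject, image = image, category = category,
                   trial_index = trial_index, x = x, y = y),
    geom, max_fixations = max_fixations
  )
}

# random positive/negative score sets with deliberate ties (values on a
# coarse lattice), for AUC equivalence properties
random_tied_sample <- function(n_max = 200) {
  n_pos <- sample(1:n_max, 1)
  n_neg <- sample(1:n_max, 1)
  list(
    positives = sample(round(stats::runif(n_pos), 2)),
    negatives = sample(round(stats::runif(n_neg), 2))
  )
}

# multi-subject multi-image dataset where every trial draws from a shared
# central Gaussian (quick, no synthetic_config machinery)
central_dataset <- function(geom, n_subjects, n_images, per = 10, sd_frac = 0.15,
                            category = "free", seed = 1) {
  set.seed(seed)
  n <- n_subjects * n_images * per
  clamp <- function(v, hi) pmin(pmax(v, 0), hi * (1 - 1e-9))
  tibble::tibble(
    subject = rep(sprintf("s%02d", seq_len(n_subjects)), each = n_images * per),
    image = rep(rep(sprintf("i%02d", seq_len(n_images)), each = per),
                times = n_subjects),
    category = category,
    trial_index = rep(seq_len(per), times = n_subjects * n_images),
    x = clamp(stats::rnorm(n, geom$width_px / 2, sd_frac * geom$width_px),
              geom$width_px),
    y = clamp(stats::rnorm(n, geom$height_px / 2, sd_frac * geom$height_px),
              geom$height_px)
  ) |> fixation_data(geom, max_fixations = Inf)
}
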