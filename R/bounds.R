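#' Cross-validation schedule for the reference-frame engine
#'
#' Training-set sizes and repetition counts for the lower-bound grid and
#' the subject-specific evaluations. The defaults are the schedule used
#' for a 48-subject, 64-images-per-category free-viewing dataset (subject
#' sizes 1, 2, 4, 7, 13, 25, 47; image sizes 1, 2, 4, 8, 16, 32, 63; 47
#' repetitions, 63 for the subject-specific bias); every field is
#' configurable so the engine runs on datasets of any size. When
#' `balanced_small` is set, training draws of size one or two are assigned
#' round-robin over repetitions instead of independently at random, so no
#' donor is over-represented.
#'
#' @param subject_sizes,image_sizes Integer vectors of training-set sizes.
#' @param reps Repetitions per (cell, test trial).
#' @param reps_subject_specific Repetitions for [subject_bias_eval()].
#' @param balanced_small Balance draws of size <= 2 explicitly.
#' @return A `cv_schedule` list.
#' @export
cv_schedule <- function(subject_sizes = c(1, 2, 4, 7, 13, 25, 47),
                        image_sizes = c(1, 2, 4, 8, 16, 32, 63),
                        reps = 47, reps_subject_specific = 63,
                        balanced_small = TRUE) {
  stopifnot(all(subject_sizes >= 1), all(image_sizes >= 1), reps >= 1)
  structure(list(
    subject_sizes = sort(unique(as.integer(subject_sizes))),
    image_sizes = sort(unique(as.integer(image_sizes))),
    reps = as.integer(reps),
    reps_subject_specific = as.integer(reps_subject_specific),
    balanced_small = isTRUE(balanced_small)
  ), class = "cv_schedule")
}

# Per-trial smoothed (unnormalized) maps: because Gaussian smoothing is
# linear and normalization is global, the FDM of any pool of trials is the
# normalized sum of these per-trial maps. cells x trials matrix + lookup.
trial_map_stack <- function(fixations, smoothing, scale) {
  g <- fx_geometry(fixations)
  rows <- round(g$height_px * scale); cols <- round(g$width_px * scale)
  sigma_col <- deg_to_px(g, smoothing$fwhm_deg, "x") * scale * FWHM_TO_SIGMA
  sigma_row <- deg_to_px(g, smoothing$fwhm_deg, "y") * scale * FWHM_TO_SIGMA
  df <- tibble::as_tibble(fixations)
  trials <- dplyr::distinct(df, .data$subject, .data$image, .data$category)
  trials$trial <- seq_len(nrow(trials))
  df <- dplyr::left_join(df, trials,
                         by = c("subject", "image", "category"))
  col <- pmin(floor(df$x * cols / g$width_px) + 1L, cols)
  row <- pmin(floor(df$y * rows / g$height_px) + 1L, rows)
  cell <- (col - 1L) * rows + row
  H <- matrix(0, rows * cols, nrow(trials))
  incr <- cbind(cell, df$trial)
  for (i in seq_len(nrow(incr))) H[incr[i, 1], incr[i, 2]] <- H[incr[i, 1], incr[i, 2]] + 1
  Kr <- smoothing_matrix(rows, sigma_row)
  Kc <- smoothing_matrix(cols, sigma_col)
  M <- H
  dim(M) <- c(rows, cols * nrow(trials))
  M <- Kr %*% M # smooth along y for every trial at once
  dim(M) <- c(rows, cols, nrow(trials))
  for (t in seq_len(nrow(trials))) M[, , t] <- M[, , t] %*% Kc
  dim(M) <- c(rows * cols, nrow(trials))
  cell_by_trial <- split(cell, df$trial)
  list(M = M, trials = trials, rows = rows, cols = cols,
       cell_by_trial = cell_by_trial, geometry = g, scale = scale)
}

score_prediction_vec <- function(p, pos_idx, measure) {
  if (measure == "auc") {
    auc_score(p[pos_idx], p)
  } else if (measure == "nss") {
    mu <- mean(p); sdp <- sqrt(mean((p - mu)^2))
    mean((p[pos_idx] - mu) / sdp)
  } else { # kl: plug-in divergence of the test histogram from the prediction
    cnt <- tabulate(pos_idx, nbins = length(p))
    kl_estimate(binned_sample(cnt), p, method = "ml")$value
  }
}

# round-robin balanced draw: a permutation of the pool consumed in blocks
draw_training <- function(pool, size, rep, perm, balanced) {
  if (balanced && size <= 2) {
    idx <- ((rep - 1) * size + seq_len(size) - 1) %% length(pool) + 1
    perm[idx]
  } else {
    sample(pool, size)
  }
}

#' Evaluate a density prediction against test fixations
#'
#' Treats a (density) prediction map as a salience map and dispatches to
#' the requested evaluation measure; the entry point the bounds engine
#' uses for every cross-validation test.
#'
#' @param prediction A `density_map` (or `salience_map`) covering the
#'   screen.
#' @param test_fixations Fixation selection to predict.
#' @param measure,negatives,seed,... Passed to [evaluate_map()].
#' @return A one-row tibble, see [evaluate_map()].
#' @export
evaluate_prediction <- function(prediction, test_fixations, measure = "auc",
                                negatives = "all_pixels", seed = NULL, ...) {
  evaluate_map(test_fixations, prediction, measure = measure,
               negatives = negatives, seed = seed, ...)
}

#' Lower bound: predictive power of the spatial bias
#'
#' Predicts the fixations of one subject on one image (the test trial)
#' with the FDM of other subjects' fixations on other images -- a
#' prediction blind to both the test subject and the test image, i.e. the
#' pure spatial bias. For every combination of training-set sizes
#' (`n_subjects x n_images` of the schedule) and every test trial,
#' `reps` random training sets are drawn excluding the test subject and
#' the test image; the grid cell is the mean score. Run per category;
#' categories are never pooled.
#'
#' @param fixations A `fixation_df`.
#' @param schedule A [cv_schedule()].
#' @param measure `"auc"`, `"nss"` or `"kl"` (for KL use a coarse working
#'   scale, see [coarse_grid()]).
#' @param smoothing A [smoothing_spec()].
#' @param scale Working grid scale (cells per pixel).
#' @param seed Integer seed.
#' @return A `bounds_grid` tibble: `category`, `n_subjects`, `n_images`,
#'   `mean`, `sd`, `n_tests`; infeasible cells (too few donors) are
#'   absent. Attributes `measure` and `schedule`.
#' @export
lower_bound <- function(fixations, schedule = cv_schedule(), measure = "auc",
                        smoothing = smoothing_spec(), scale = 1 / 16,
                        seed = 1) {
  stk <- trial_map_stack(fixations, smoothing, scale)
  measure <- match.arg(measure, c("auc", "nss", "kl"))
  set.seed(seed)
  out <- list()
  for (cat in unique(stk$trials$category)) {
    tr <- stk$trials[stk$trials$category == cat, ]
    subjects <- unique(tr$subject)
    images <- unique(tr$image)
    for (ns in schedule$subject_sizes) {
      if (ns > length(subjects) - 1) next
      for (ni in schedule$image_sizes) {
        if (ni > length(images) - 1) next
        scores <- numeric(0)
        for (t in seq_len(nrow(tr))) {
          pos_idx <- stk$cell_by_trial[[tr$trial[t]]]
          subj_pool <- setdiff(subjects, tr$subject[t])
          img_pool <- setdiff(images, tr$image[t])
          perm_s <- sample(subj_pool)
          perm_i <- sample(img_pool)
          for (r in seq_len(schedule$reps)) {
            ts_draw <- draw_training(subj_pool, ns, r, perm_s, schedule$balanced_small)
            ti <- draw_training(img_pool, ni, r, perm_i, schedule$balanced_small)
            cols <- tr$trial[tr$subject %in% ts_draw & tr$image %in% ti]
            v <- rowSums(stk$M[, cols, drop = FALSE])
            scores <- c(scores, score_prediction_vec(v / sum(v), pos_idx, measure))
          }
        }
        out[[length(out) + 1]] <- tibble::tibble(
          category = cat, n_subjects = ns, n_images = ni,
          mean = mean(scores), sd = stats::sd(scores), n_tests = length(scores)
        )
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "measure") <- measure
  attr(res, "schedule") <- schedule
  class(res) <- c("bounds_grid", class(res))
  res
}

#' Upper bound: inter-subject consistency
#'
#' Predicts the fixations of one subject on one image with the pooled FDM
#' of other subjects on the *same* image, for an increasing number of
#' training subjects. The test subject never enters the training pool.
#'
#' @inheritParams lower_bound
#' @param train_sizes Training-set sizes in subjects; default 1 up to
#'   (number of subjects - 1) in steps of one.
#' @param reps Random training draws per (size, test trial).
#' @return An `upper_bound_curve` tibble: `category`,
#'   `n_train_subjects`, `mean`, `sd`, `n_tests`.
#' @export
upper_bound <- function(fixations, train_sizes = NULL, reps = 47,
                        measure = "auc", smoothing = smoothing_spec(),
                        scale = 1 / 16, seed = 1) {
  stk <- trial_map_stack(fixations, smoothing, scale)
  measure <- match.arg(measure, c("auc", "nss", "kl"))
  set.seed(seed)
  out <- list()
  for (cat in unique(stk$trials$category)) {
    tr <- stk$trials[stk$trials$category == cat, ]
    subjects <- unique(tr$subject)
    if (length(subjects) < 2) {
      stop("upper bound needs at least 2 subjects per category", call. = FALSE)
    }
    sizes <- if (is.null(train_sizes)) seq_len(length(subjects) - 1) else
      train_sizes[train_sizes <= length(subjects) - 1]
    for (ns in sizes) {
      scores <- numeric(0)
      for (t in seq_len(nrow(tr))) {
        pos_idx <- stk$cell_by_trial[[tr$trial[t]]]
        subj_pool <- setdiff(subjects, tr$subject[t])
        perm_s <- sample(subj_pool)
        for (r in seq_len(reps)) {
          ts <- draw_training(subj_pool, ns, r, perm_s, ns <= 2)
          cols <- tr$trial[tr$subject %in% ts & tr$image == tr$image[t]]
          v <- rowSums(stk$M[, cols, drop = FALSE])
          if (sum(v) == 0) next # training subjects had no fixations here
          scores <- c(scores, score_prediction_vec(v / sum(v), pos_idx, measure))
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        category = cat, n_train_subjects = ns,
        mean = mean(scores), sd = stats::sd(scores), n_tests = length(scores)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "measure") <- measure
  class(res) <- c("upper_bound_curve", class(res))
  res
}

#' Predictive power of the subject-specific spatial bias
#'
#' Predicts a subject's fixations on one image with the FDM of the *same*
#' subject's fixations on other images, as a function of the number of
#' training images. Train and test share the subject, never the image.
#'
#' @inheritParams lower_bound
#' @param image_sizes Training-set sizes in images; defaults to the
#'   schedule's `image_sizes`.
#' @return A `subject_bias_curve` tibble: `category`, `n_images`, `mean`,
#'   `sd`, `n_tests`.
#' @export
subject_bias_eval <- function(fixations, schedule = cv_schedule(),
                              image_sizes = schedule$image_sizes,
                              measure = "auc", smoothing = smoothing_spec(),
                              scale = 1 / 16, seed = 1) {
  stk <- trial_map_stack(fixations, smoothing, scale)
  measure <- match.arg(measure, c("auc", "nss", "kl"))
  reps <- schedule$reps_subject_specific
  set.seed(seed)
  out <- list()
  for (cat in unique(stk$trials$category)) {
    tr <- stk$trials[stk$trials$category == cat, ]
    images <- unique(tr$image)
    for (ni in image_sizes) {
      if (ni > length(images) - 1) next
      scores <- numeric(0)
      for (t in seq_len(nrow(tr))) {
        pos_idx <- stk$cell_by_trial[[tr$trial[t]]]
        img_pool <- setdiff(images, tr$image[t])
        perm_i <- sample(img_pool)
        for (r in seq_len(reps)) {
          ti <- draw_training(img_pool, ni, r, perm_i, schedule$balanced_small)
          cols <- tr$trial[tr$subject == tr$subject[t] & tr$image %in% ti]
          v <- rowSums(stk$M[, cols, drop = FALSE])
          if (sum(v) == 0) next
          scores <- c(scores, score_prediction_vec(v / sum(v), pos_idx, measure))
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        category = cat, n_images = ni,
        mean = mean(scores), sd = stats::sd(scores), n_tests = length(scores)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "measure") <- measure
  class(res) <- c("subject_bias_curve", class(res))
  res
}

#' Principal components of subject spatial biases
#'
#' Computes the smoothed spatial-bias FDM of every training subject over
#' the training images, flattens the maps, centres them by their mean map
#' and extracts the top `k` principal components. The component signs are
#' fixed (largest-magnitude coefficient positive) for reproducibility
#' only; PCA signs are arbitrary.
#'
#' @param fixations A `fixation_df`.
#' @param subjects Training subject ids (>= k + 1).
#' @param images Training image ids.
#' @param k Number of components kept (default 5).
#' @inheritParams lower_bound
#' @return A `pca_basis`: `mean_map` (matrix), `components`
#'   (cells x k, orthonormal), `eigenvalues` (variances, nonincreasing),
#'   plus grid/geometry bookkeeping.
#' @export
pca_basis <- function(fixations, subjects, images, k = 5,
                      smoothing = smoothing_spec(), scale = 1 / 16) {
  if (length(subjects) < k + 1) {
    stop("need at least k + 1 = ", k + 1, " training subjects", call. = FALSE)
  }
  g <- fx_geometry(fixations)
  rows <- round(g$height_px * scale); cols <- round(g$width_px * scale)
  X <- t(vapply(subjects, function(s) {
    as.vector(unclass_map(spatial_bias(fixations, subjects = s, images = images,
                                       smoothing = smoothing, scale = scale)))
  }, numeric(rows * cols)))
  mean_vec <- colMeans(X)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  comps <- pr$rotation
  for (j in seq_len(ncol(comps))) {
    if (comps[which.max(abs(comps[, j])), j] < 0) comps[, j] <- -comps[, j]
  }
  structure(list(
    mean_map = matrix(mean_vec, rows, cols),
    components = comps,
    eigenvalues = pr$sdev[seq_len(ncol(comps))]^2,
    k = ncol(comps), rows = rows, cols = cols,
    geometry = g, scale = scale, subjects = subjects
  ), class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components over %d x %d cells (%d subjects)\n",
              x$k, x$rows, x$cols, length(x$subjects)))
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat("  eigenvalue shares:", paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' PCA-cleaned subject-specific spatial bias
#'
#' Regresses a (noisy) subject-specific bias onto the basis components --
#' with orthonormal components the least-squares weights are the
#' projections of the centred bias -- and reconstructs it as
#' `mean_map + sum(w_j * component_j)`. Negative cells are clipped to zero
#' and the map renormalized to unit mass.
#'
#' @param basis A [pca_basis()].
#' @param subject_bias A `density_map` of the same grid (the subject's raw
#'   spatial bias).
#' @return A `density_map` (the cleaned bias).
#' @export
pca_clean_bias <- function(basis, subject_bias) {
  v <- as.vector(unclass_map(subject_bias))
  if (length(v) != basis$rows * basis$cols) {
    stop("subject bias grid does not match the basis", call. = FALSE)
  }
  w <- crossprod(basis$components, v - as.vector(basis$mean_map))
  recon <- as.vector(basis$mean_map) + basis$components %*% w
  recon[recon < 0] <- 0
  density_map(matrix(recon / sum(recon), basis$rows, basis$cols),
              basis$geometry, scale = basis$scale)
}

#' Eigenvalue-weighted bias (control condition)
#'
#' The subject-blind control for [pca_clean_bias()]: the mean map plus the
#' components weighted by their eigenvalues instead of subject-specific
#' regression weights; clipped and renormalized the same way.
#'
#' @param basis A [pca_basis()].
#' @return A `density_map`.
#' @export
eigen_weighted_bias <- function(basis) {
  recon <- as.vector(basis$mean_map) +
    basis$components %*% basis$eigenvalues[seq_len(basis$k)]
  recon[recon < 0] <- 0
  density_map(matrix(recon / sum(recon), basis$rows, basis$cols),
              basis$geometry, scale = basis$scale)
}

#' Combined subject- and image-specific prediction
#'
#' Removes the generic spatial bias from an inter-subject prediction by
#' point-wise division through the training subjects' spatial bias, then
#' re-imposes the *predicted subject's* own spatial bias by point-wise
#' multiplication, and renormalizes to unit mass. With enough subject
#' idiosyncrasy this prediction can beat the inter-subject consistency
#' bound ("better than perfect").
#'
#' @param intersubject_fdm `density_map`: pooled training subjects on the
#'   test image.
#' @param training_bias `density_map`: training subjects' spatial bias on
#'   other images.
#' @param subject_bias `density_map`: the predicted subject's spatial bias
#'   on other images.
#' @param floor Positive floor applied to the divisor; default `1e-6` of
#'   the uniform cell mass.
#' @return A `density_map`.
#' @export
combined_prediction <- function(intersubject_fdm, training_bias, subject_bias,
                                floor = NULL) {
  a <- unclass_map(intersubject_fdm)
  b <- unclass_map(training_bias)
  s <- unclass_map(subject_bias)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(s))) {
    stop("all three maps must share the same grid", call. = FALSE)
  }
  if (is.null(floor)) floor <- 1e-6 / length(a)
  stopifnot(floor > 0)
  v <- a / pmax(b, floor) * s
  density_map(v / sum(v), map_geometry(intersubject_fdm),
              scale = map_scale(intersubject_fdm))
}
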