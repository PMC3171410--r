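#' Classification samples: salience at fixated vs control locations
#'
#' Most evaluation measures compare the salience values at fixated
#' locations ("positives") with salience values at control locations
#' ("negatives"). `sample_scores()` extracts both multisets from a map and
#' a fixation selection. Salience lookup is the value of the grid cell
#' containing the fixation (no interpolation).
#'
#' Negative strategies:
#' \describe{
#'   \item{`all_pixels`}{every cell value of the map;}
#'   \item{`nonfixated_pixels`}{every cell value except the fixated cells;}
#'   \item{`other_image_fixations`}{cell values at donor locations, e.g.
#'     positions fixated on other images (pass them via `donors`), the hook
#'     for shuffled-control analyses.}
#' }
#'
#' @param map A `salience_map` covering the screen.
#' @param fixations Fixation selection (`fixation_df` or data frame with
#'   `x`, `y`), all within screen bounds.
#' @param negatives One of the strategies above.
#' @param donors Data frame with `x`, `y` pixel positions, required for
#'   `other_image_fixations`.
#' @return A list of class `classification_sample` with numeric vectors
#'   `positives` and `negatives`.
#' @export
sample_scores <- function(map, fixations,
                          negatives = c("all_pixels", "nonfixated_pixels",
                                        "other_image_fixations"),
                          donors = NULL) {
  negatives <- match.arg(negatives)
  v <- unclass_map(map)
  ci <- map_cell_index(map, fixations$x, fixations$y)
  pos <- v[ci$idx]
  neg <- switch(negatives,
    all_pixels = as.vector(v),
    nonfixated_pixels = as.vector(v)[-unique(ci$idx)],
    other_image_fixations = {
      if (is.null(donors)) {
        stop("other_image_fixations requires donor locations", call. = FALSE)
      }
      di <- map_cell_index(map, donors$x, donors$y)
      v[di$idx]
    }
  )
  if (length(neg) == 0) stop("empty negative set", call. = FALSE)
  structure(list(positives = pos, negatives = neg),
            class = "classification_sample")
}

#' Area under the ROC curve (efficient exact algorithm)
#'
#' Classifies locations as fixated when their salience value is at or above
#' a threshold and integrates the true-positive rate over the false-positive
#' rate. Only the unique positive salience values are used as thresholds:
#' between two positive values the ROC curve is a horizontal run (negatives
#' passing the threshold at constant TPR), so lower-sum integration over
#' these runs is exact; where a threshold value is shared by positives and
#' negatives the curve is a diagonal, integrated trapezoidally so each tied
#' positive/negative pair earns half credit, and the final run to (1, 1) is
#' handled the same way. The result is exactly the Mann-Whitney two-sample
#' statistic `(wins + ties/2) / (n_pos * n_neg)`: 1 is perfect separation,
#' 0.5 chance (a constant map scores exactly 0.5).
#'
#' @param positives,negatives Finite numeric vectors of salience values at
#'   fixated and control locations; both non-empty.
#' @return The AUC, a scalar in `[0, 1]`.
#' @seealso [roc_curve()] for the full curve, [auc_pairwise()] for the
#'   quadratic reference implementation.
#' @export
auc_score <- function(positives, negatives) {
  check_sample(positives, negatives)
  P <- length(positives); N <- length(negatives)
  thr <- sort(unique(positives), decreasing = TRUE) # descending thresholds
  sp <- sort(positives); sn <- sort(negatives)
  # counts via binary search on the sorted vectors
  n_pos_ge <- P - findInterval(thr, sp, left.open = TRUE)
  n_neg_ge <- N - findInterval(thr, sn, left.open = TRUE)
  n_neg_gt <- N - findInterval(thr, sn)
  tpr <- n_pos_ge / P
  fpr <- n_neg_ge / N
  gap <- n_neg_gt / N # FPR just before the tied jump at each threshold
  tpr0 <- c(0, tpr[-length(tpr)])
  fpr0 <- c(0, fpr[-length(fpr)])
  area <- sum((gap - fpr0) * tpr0 + (fpr - gap) * (tpr0 + tpr) / 2)
  area + (1 - fpr[length(fpr)]) * 1 # terminal run at TPR = 1
}

check_sample <- function(positives, negatives) {
  if (length(positives) < 1 || length(negatives) < 1) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(positives)) || !all(is.finite(negatives))) {
    stop("salience values must be finite", call. = FALSE)
  }
}

#' Pairwise (Mann-Whitney) AUC reference
#'
#' Direct O(n_pos * n_neg) computation of
#' `mean(positive > negative) + mean(positive == negative) / 2` over all
#' pairs. Slow; used as an independent cross-check of [auc_score()].
#'
#' @inheritParams auc_score
#' @return The AUC.
#' @export
auc_pairwise <- function(positives, negatives) {
  check_sample(positives, negatives)
  cmp <- outer(positives, negatives, ">") + 0.5 * outer(positives, negatives, "==")
  mean(cmp)
}

#' Full ROC curve
#'
#' Evaluates TPR and FPR at every unique value in the pooled sample
#' (classification rule: salience `>= threshold`), prepending the origin.
#' Trapezoidal integration of this curve ([roc_auc()]) equals [auc_score()]
#' and the pairwise statistic exactly, ties included.
#'
#' @inheritParams auc_score
#' @return A tibble with columns `threshold` (descending; `Inf` for the
#'   origin), `tpr` and `fpr`, both nondecreasing and ending at 1.
#' @export
roc_curve <- function(positives, negatives) {
  check_sample(positives, negatives)
  thr <- sort(unique(c(positives, negatives)), decreasing = TRUE)
  sp <- sort(positives); sn <- sort(negatives)
  tpr <- (length(positives) - findInterval(thr, sp, left.open = TRUE)) /
    length(positives)
  fpr <- (length(negatives) - findInterval(thr, sn, left.open = TRUE)) /
    length(negatives)
  tibble::tibble(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' @rdname roc_curve
#' @param roc A tibble as returned by `roc_curve()`.
#' @return `roc_auc()`: the trapezoidal area under the curve.
#' @export
roc_auc <- function(roc) {
  n <- nrow(roc)
  fpr <- roc$fpr; tpr <- roc$tpr
  if (fpr[n] < 1 || tpr[n] < 1) { fpr <- c(fpr, 1); tpr <- c(tpr, 1); n <- n + 1 }
  sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
}

#' Normalized scanpath salience (NSS)
#'
#' Mean salience at the fixated cells after normalizing the map to zero
#' mean and unit standard deviation (population SD over all cells).
#'
#' @param map A non-constant `salience_map`.
#' @param fixations Fixation selection with `x`, `y`.
#' @return The NSS value (scalar, in SD units of the map).
#' @export
nss_score <- function(map, fixations) {
  v <- unclass_map(map)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) {
    stop("NSS undefined for a constant map (zero standard deviation)",
         call. = FALSE)
  }
  ci <- map_cell_index(map, fixations$x, fixations$y)
  mean((v[ci$idx] - mu) / sd_pop)
}

#' Chance-adjusted salience
#'
#' Mean salience at fixated locations minus the mean salience of the whole
#' map; values above 0 mean fixated locations carry above-average salience.
#'
#' @inheritParams nss_score
#' @return The difference of means (map units).
#' @export
cas_score <- function(map, fixations) {
  v <- unclass_map(map)
  ci <- map_cell_index(map, fixations$x, fixations$y)
  mean(v[ci$idx]) - mean(v)
}

#' Ratio of medians
#'
#' Scores each location by the maximum of the salience map within a disc of
#' `radius_deg` degrees around it (clipped at the borders; the disc is
#' elliptical in cells when the axes have different pixel densities), and
#' reports `median(fixated scores) / median(control scores)` with control
#' points drawn uniformly over the image.
#'
#' @inheritParams nss_score
#' @param radius_deg Disc radius in degrees of visual angle (default 5.6).
#' @param n_controls Number of uniform control points; defaults to the
#'   number of fixations.
#' @param seed Optional integer seed for the control draw.
#' @return The ratio of medians (scalar).
#' @export
rom_score <- function(map, fixations, radius_deg = 5.6, n_controls = NULL,
                      seed = NULL) {
  stopifnot(radius_deg > 0)
  g <- map_geometry(map)
  s <- map_scale(map)
  if (is.null(n_controls)) n_controls <- nrow(fixations)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- tibble::tibble(
    x = stats::runif(n_controls, 0, g$width_px) * (1 - 1e-12),
    y = stats::runif(n_controls, 0, g$height_px) * (1 - 1e-12)
  )
  rx <- deg_to_px(g, radius_deg, "x") * s
  ry <- deg_to_px(g, radius_deg, "y") * s
  med_fix <- stats::median(disc_max(map, fixations$x, fixations$y, rx, ry))
  med_ctrl <- stats::median(disc_max(map, ctrl$x, ctrl$y, rx, ry))
  if (med_ctrl == 0) stop("control median is zero; ratio undefined", call. = FALSE)
  med_fix / med_ctrl
}

# max of the map inside an elliptical disc (radii in cells) around each
# pixel position; plain bounding-box scan with the ellipse mask
disc_max <- function(map, x, y, rx, ry) {
  v <- unclass_map(map)
  ci <- map_cell_index(map, x, y)
  vapply(seq_along(ci$row), function(i) {
    r0 <- max(1L, ci$row[i] - ceiling(ry)); r1 <- min(nrow(v), ci$row[i] + ceiling(ry))
    c0 <- max(1L, ci$col[i] - ceiling(rx)); c1 <- min(ncol(v), ci$col[i] + ceiling(rx))
    rr <- r0:r1; cc <- c0:c1
    mask <- outer((rr - ci$row[i])^2 / ry^2, (cc - ci$col[i])^2 / rx^2, "+") <= 1
    max(v[rr, cc, drop = FALSE][mask])
  }, numeric(1))
}

#' Percentile measure
#'
#' Fraction of fixations that land in the image area covered by the top
#' `100 - percentile` percent of salience values (default: top 20%). For a
#' map with all-distinct values the selected area covers exactly that
#' fraction of the image, which is therefore the chance level.
#'
#' @inheritParams nss_score
#' @param percentile Threshold percentile in (0, 100); default 80.
#' @return Fraction of fixations counted as hits, in `[0, 1]`.
#' @export
percentile_score <- function(map, fixations, percentile = 80) {
  stopifnot(percentile > 0, percentile < 100)
  v <- unclass_map(map)
  n_cells <- length(v)
  k <- max(1L, round(n_cells * (1 - percentile / 100)))
  thr <- sort(as.vector(v), decreasing = TRUE)[k]
  ci <- map_cell_index(map, fixations$x, fixations$y)
  mean(v[ci$idx] >= thr)
}

#' Percent correct of a naive Bayes classifier
#'
#' Estimates the class-conditional score distributions P(S | fixated) and
#' P(S | not fixated) by equal-width binned histograms on the training
#' folds (Laplace-smoothed, equal priors) and classifies each held-out
#' point as fixated when P(bin | fixated) > P(bin | not fixated). Every
#' point is tested exactly once under k-fold cross-validation; the value is
#' the overall fraction of correct classifications.
#'
#' @param sample A `classification_sample` (see [sample_scores()]), or a
#'   list with `positives` and `negatives`; both classes need at least
#'   `k_folds` members.
#' @param n_bins Number of histogram bins over the pooled score range.
#' @param k_folds Number of cross-validation folds.
#' @param seed Optional integer seed for the fold assignment.
#' @return Fraction correct, in `[0, 1]`.
#' @export
nb_percent_correct <- function(sample, n_bins = 10, k_folds = 10, seed = NULL) {
  pos <- sample$positives; neg <- sample$negatives
  check_sample(pos, neg)
  if (length(pos) < k_folds || length(neg) < k_folds) {
    stop("each class needs at least k_folds = ", k_folds, " members",
         call. = FALSE)
  }
  rng <- range(c(pos, neg))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), n_bins)
  bpos <- bin_of(pos); bneg <- bin_of(neg)
  if (!is.null(seed)) set.seed(seed)
  fold_pos <- sample(rep_len(seq_len(k_folds), length(pos)))
  fold_neg <- sample(rep_len(seq_len(k_folds), length(neg)))
  correct <- 0L
  for (f in seq_len(k_folds)) {
    hp <- tabulate(bpos[fold_pos != f], nbins = n_bins) + 1 # Laplace smoothing
    hn <- tabulate(bneg[fold_neg != f], nbins = n_bins) + 1
    lik_pos <- hp / sum(hp)
    lik_neg <- hn / sum(hn)
    pred_fix <- lik_pos > lik_neg # equal priors; ties -> non-fixated
    correct <- correct + sum(pred_fix[bpos[fold_pos == f]]) +
      sum(!pred_fix[bneg[fold_neg == f]])
  }
  correct / (length(pos) + length(neg))
}

#' Kullback-Leibler divergence between density maps
#'
#' `sum(p * log(p / q))` over cells, with `0 * log(0) = 0`. Because the
#' measure is extremely sensitive to near-zero model predictions at
#' fixated locations (raw zeros make it infinite), `q` is floored at
#' `q_floor` and renormalized before the sum. `p` is the empirical (true)
#' fixation density, `q` the model density.
#'
#' @param p,q `density_map`s (or plain unit-mass matrices) of the same
#'   shape.
#' @param log_base Base of the logarithm: `exp(1)` for nats (default) or
#'   `2` for bits.
#' @param q_floor Floor applied to `q`; default `1e-12` of the uniform
#'   cell mass.
#' @return The divergence (scalar `>= 0` up to the flooring perturbation).
#' @export
kl_div <- function(p, q, log_base = exp(1), q_floor = NULL) {
  p <- as_prob_matrix(p); q <- as_prob_matrix(q)
  if (!all(dim(p) == dim(q))) stop("p and q must have the same shape", call. = FALSE)
  if (is.null(q_floor)) q_floor <- 1e-12 / length(q)
  q <- pmax(q, q_floor)
  q <- q / sum(q)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz]))) / log(log_base)
}

as_prob_matrix <- function(p, tol = 1e-6) {
  v <- if (inherits(p, "salience_map")) unclass_map(p) else as.matrix(p)
  if (any(v < 0) || abs(sum(v) - 1) > tol) {
    stop("expected a unit-mass non-negative density", call. = FALSE)
  }
  v
}

#' @rdname kl_div
#' @details `symmetric_kl()` is `kl_div(p, q) + kl_div(q, p)`, useful when
#'   neither density is the designated ground truth (e.g. inter-subject
#'   comparisons).
#' @export
symmetric_kl <- function(p, q, log_base = exp(1), q_floor = NULL) {
  kl_div(p, q, log_base, q_floor) + kl_div(q, p, log_base, q_floor)
}

#' Pearson correlation between a density map and a prediction
#'
#' Product-moment correlation over flattened, index-matched cell values:
#' the standard "map similarity" reading of correlation. Both maps must be
#' non-constant.
#'
#' @param p A `density_map` (empirical fixation density).
#' @param q A `salience_map` prediction of the same shape.
#' @return Pearson r in `[-1, 1]`.
#' @export
map_correlation <- function(p, q) {
  pv <- if (inherits(p, "salience_map")) unclass_map(p) else as.matrix(p)
  qv <- if (inherits(q, "salience_map")) unclass_map(q) else as.matrix(q)
  if (!all(dim(pv) == dim(qv))) stop("maps must have the same shape", call. = FALSE)
  if (stats::sd(pv) == 0 || stats::sd(qv) == 0) {
    stop("correlation undefined for a constant map", call. = FALSE)
  }
  stats::cor(as.vector(pv), as.vector(qv))
}

#' Theoretical maximum AUC of a probabilistic prediction
#'
#' When the prediction is a probability density and the empirical fixation
#' distribution has full support, no classifier can reach AUC 1: every
#' location has both a finite probability of being fixated and of serving
#' as a control. For self-prediction (model density equal to the true
#' density `p`) against uniformly distributed controls, the achievable AUC
#' is the probability-weighted pairwise statistic
#' `sum_i sum_j p_i * (1/N) * (1(p_i > p_j) + 1(p_i == p_j)/2)`,
#' computed here in `O(N log N)` by grouping equal cell values. It is 0.5
#' for a uniform density and strictly below 1 for any density that is not
#' concentrated on a null set of cells.
#'
#' The derivation assumes no spatial bias in the control distribution
#' (uniform controls); that assumption is reported in the result of
#' [evaluate_map()].
#'
#' @param p A `density_map` (or unit-mass matrix) over `N` cells.
#' @return The upper bound on AUC, a scalar in `[0.5, 1)`.
#' @export
theoretical_max_auc <- function(p) {
  v <- as.vector(as_prob_matrix(p, tol = 1e-9))
  n <- length(v)
  vs <- sort(v)
  runs <- rle(vs) # ties are exact: contiguous runs of equal cell values
  cnt <- runs$lengths
  ends <- cumsum(cnt)
  mass <- diff(c(0, cumsum(vs)[ends]))
  below <- c(0, ends[-length(ends)])
  sum(mass * (below + cnt / 2) / n)
}

#' Evaluate a salience map against fixations with a named measure
#'
#' Tidy front door to the individual measures: dispatches on `measure`,
#' returns a one-row tibble with the score and its provenance, ready for
#' row-binding across images, subjects and models.
#'
#' @param fixations Fixation selection (`fixation_df`).
#' @param map A `salience_map` (for density-based measures, the model map;
#'   it is normalized to unit mass internally where the measure needs a
#'   density).
#' @param measure One of `"auc"`, `"nss"`, `"cas"`, `"rom"`,
#'   `"percentile"`, `"nb"`, `"kl"`, `"skl"`, `"corr"`, `"max_auc"`.
#' @param negatives Negative-sampling strategy for the classification
#'   measures, see [sample_scores()].
#' @param donors Donor locations for `other_image_fixations`.
#' @param smoothing Smoothing used when the measure needs an empirical
#'   density (`kl`, `skl`, `corr`).
#' @param seed Optional seed for the stochastic measures (`rom`, `nb`).
#' @param ... Additional arguments passed to the underlying measure
#'   (e.g. `percentile`, `radius_deg`, `n_bins`, `k_folds`, `log_base`).
#' @return A one-row tibble: `measure`, `value`, `n_pos`, `n_neg`,
#'   `params` (list column).
#' @export
evaluate_map <- function(fixations, map,
                         measure = c("auc", "nss", "cas", "rom", "percentile",
                                     "nb", "kl", "skl", "corr", "max_auc"),
                         negatives = "all_pixels", donors = NULL,
                         smoothing = smoothing_spec(), seed = NULL, ...) {
  measure <- match.arg(measure)
  n_pos <- nrow(fixations)
  n_neg <- NA_integer_
  params <- list(...)
  value <- switch(measure,
    auc = {
      cs <- sample_scores(map, fixations, negatives, donors)
      n_neg <- length(cs$negatives)
      auc_score(cs$positives, cs$negatives)
    },
    nss = nss_score(map, fixations),
    cas = cas_score(map, fixations),
    rom = rom_score(map, fixations, seed = seed, ...),
    percentile = percentile_score(map, fixations, ...),
    nb = {
      cs <- sample_scores(map, fixations, negatives, donors)
      n_neg <- length(cs$negatives)
      nb_percent_correct(cs, seed = seed, ...)
    },
    kl = {
      p <- fdm(fixations, smoothing = smoothing, scale = map_scale(map),
               geometry = map_geometry(map))
      kl_div(p, as_density_map(map), ...)
    },
    skl = {
      p <- fdm(fixations, smoothing = smoothing, scale = map_scale(map),
               geometry = map_geometry(map))
      symmetric_kl(p, as_density_map(map), ...)
    },
    corr = {
      p <- fdm(fixations, smoothing = smoothing, scale = map_scale(map),
               geometry = map_geometry(map))
      map_correlation(p, map)
    },
    max_auc = {
      params <- c(params, list(controls = "uniform", spatial_bias_equilibration = FALSE))
      theoretical_max_auc(as_density_map(map))
    }
  )
  if (measure %in% c("auc", "nb")) params <- c(params, list(negatives = negatives))
  tibble::tibble(
    measure = measure, value = value,
    n_pos = n_pos, n_neg = n_neg, params = list(params)
  )
}
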