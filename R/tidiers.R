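#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and summarize reference-frame results
#'
#' `bounds_grid`, `upper_bound_curve` and `subject_bias_curve` objects are
#' already tidy tibbles; `tidy()` strips the class and adds the measure as
#' a column. `glance()` reports, per category, the score at the largest
#' training-set sizes -- the headline bound estimates.
#'
#' @param x A result from [lower_bound()], [upper_bound()] or
#'   [subject_bias_eval()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bounds_grid
#' @export
tidy.bounds_grid <- function(x, ...) {
  out <- tibble::as_tibble(unclass_result(x))
  out$measure <- attr(x, "measure")
  out
}

#' @rdname tidy.bounds_grid
#' @method tidy upper_bound_curve
#' @export
tidy.upper_bound_curve <- function(x, ...) tidy.bounds_grid(x, ...)

#' @rdname tidy.bounds_grid
#' @method tidy subject_bias_curve
#' @export
tidy.subject_bias_curve <- function(x, ...) tidy.bounds_grid(x, ...)

unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("bounds_grid", "upper_bound_curve", "subject_bias_curve"))
  attr(x, "measure") <- NULL
  attr(x, "schedule") <- NULL
  x
}

#' @rdname tidy.bounds_grid
#' @method glance bounds_grid
#' @export
glance.bounds_grid <- function(x, ...) {
  tibble::as_tibble(unclass_result(x)) |>
    dplyr::group_by(.data$category) |>
    dplyr::filter(.data$n_subjects == max(.data$n_subjects),
                  .data$n_images == max(.data$n_images)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$category, bound = .data$mean,
                     n_subjects = .data$n_subjects, n_images = .data$n_images,
                     measure = attr(x, "measure"))
}

#' @rdname tidy.bounds_grid
#' @method glance upper_bound_curve
#' @export
glance.upper_bound_curve <- function(x, ...) {
  tibble::as_tibble(unclass_result(x)) |>
    dplyr::group_by(.data$category) |>
    dplyr::filter(.data$n_train_subjects == max(.data$n_train_subjects)) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$category, bound = .data$mean,
                     n_train_subjects = .data$n_train_subjects,
                     measure = attr(x, "measure"))
}

#' Tidiers for a subject-bias principal component basis
#'
#' `tidy()` returns one row per component with its eigenvalue and variance
#' share; `glance()` one row with the dimensionality and the share carried
#' by the first two components.
#'
#' @param x A [pca_basis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pca_basis
#' @export
tidy.pca_basis <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    eigenvalue = x$eigenvalues,
    prop_variance = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' @rdname tidy.pca_basis
#' @method glance pca_basis
#' @export
glance.pca_basis <- function(x, ...) {
  pv <- x$eigenvalues / sum(x$eigenvalues)
  tibble::tibble(
    k = x$k, n_subjects = length(x$subjects),
    total_variance = sum(x$eigenvalues),
    prop_top2 = sum(pv[seq_len(min(2, x$k))])
  )
}

#' Plot methods
#'
#' `autoplot()` methods turn the package's result types into standard
#' ggplot2 displays: a tile grid for the lower-bound matrix, saturation
#' curves for the upper bound and subject-specific bias, a raster for
#' maps, and the ROC curve for classification samples.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name autoplot-gazeref
NULL

#' @rdname autoplot-gazeref
#' @method autoplot bounds_grid
#' @export
autoplot.bounds_grid <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$n_subjects),
                                   factor(.data$n_images),
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$mean)),
                       size = 2.7) +
    ggplot2::facet_wrap(~category) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "training subjects", y = "training images",
                  fill = attr(object, "measure"),
                  title = "Spatial-bias lower bound")
}

#' @rdname autoplot-gazeref
#' @method autoplot upper_bound_curve
#' @export
autoplot.upper_bound_curve <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$n_train_subjects, .data$mean,
                                   colour = .data$category)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training subjects", y = attr(object, "measure"),
                  title = "Inter-subject consistency (upper bound)")
}

#' @rdname autoplot-gazeref
#' @method autoplot subject_bias_curve
#' @export
autoplot.subject_bias_curve <- function(object, ...) {
  df <- tibble::as_tibble(unclass_result(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$n_images, .data$mean,
                                   colour = .data$category)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "training images", y = attr(object, "measure"),
                  title = "Subject-specific spatial bias")
}

#' @rdname autoplot-gazeref
#' @method autoplot salience_map
#' @export
autoplot.salience_map <- function(object, ...) {
  v <- unclass_map(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- as.vector(v)[(df$col - 1) * nrow(v) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' @rdname autoplot-gazeref
#' @param positives,negatives Passed to [roc_curve()].
#' @export
plot_roc <- function(positives, negatives) {
  roc <- roc_curve(positives, negatives)
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC (AUC = %.3f)", auc_score(positives, negatives))
    )
}
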