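#' Fixation tables
#'
#' A fixation dataset is a tidy table with one row per fixation and the
#' columns `subject`, `image`, `category`, `trial_index`, `x`, `y`, carrying
#' the display geometry it was recorded on as an attribute. Coordinates are
#' in screen pixels: `x` is the column, `y` the row, origin at the top-left
#' pixel corner, so valid positions lie in the half-open box
#' `[0, width_px) x [0, height_px)`. A coordinate names the centre of the
#' sample; trial_index is the ordinal position of the fixation within its
#' trial (1-based, typically the first 15 free-viewing fixations).
#'
#' `fixation_data()` validates a plain data frame and attaches the geometry;
#' out-of-bounds rows are handled per `oob`: `"drop"` removes them with a
#' warning (eye trackers routinely emit slightly off-screen samples),
#' `"error"` rejects the whole table for strict pipelines.
#'
#' @param df Data frame with the six required columns. Extra columns are
#'   kept but ignored by the package.
#' @param geometry A [display_geometry()].
#' @param oob Out-of-bounds policy: `"drop"` or `"error"`.
#' @param max_fixations Maximum fixations allowed per (subject, image) trial;
#'   `Inf` to disable the check.
#' @return A tibble of class `fixation_df` with attribute `geometry`.
#' @export
fixation_data <- function(df, geometry, oob = c("drop", "error"),
                          max_fixations = 15) {
  oob <- match.arg(oob)
  stopifnot(inherits(geometry, "display_geometry"))
  need <- c("subject", "image", "category", "trial_index", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("fixation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!is.numeric(df$x) || !is.numeric(df$y)) {
    stop("fixation coordinates x and y must be numeric", call. = FALSE)
  }
  if (!is.numeric(df$trial_index) || any(df$trial_index < 1) ||
      any(df$trial_index != round(df$trial_index))) {
    stop("trial_index must be an integer >= 1", call. = FALSE)
  }
  if (anyNA(df[need])) stop("fixation table contains missing values", call. = FALSE)

  bad <- df$x < 0 | df$x >= geometry$width_px |
    df$y < 0 | df$y >= geometry$height_px
  if (any(bad)) {
    if (oob == "error") {
      stop(sum(bad), " fixation(s) fall outside the screen ",
           "[0,", geometry$width_px, ") x [0,", geometry$height_px, ")",
           call. = FALSE)
    }
    warning("dropped ", sum(bad), " out-of-bounds fixation(s)", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }

  # one category per image
  img_cat <- dplyr::distinct(df, .data$image, .data$category)
  dup <- img_cat$image[duplicated(img_cat$image)]
  if (length(dup) > 0) {
    stop("image(s) with more than one category: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  if (is.finite(max_fixations)) {
    per_trial <- dplyr::count(df, .data$subject, .data$image)
    if (any(per_trial$n > max_fixations)) {
      stop("some (subject, image) trials exceed max_fixations = ",
           max_fixations, call. = FALSE)
    }
  }

  new_fixation_df(df, geometry)
}

new_fixation_df <- function(df, geometry) {
  out <- tibble::as_tibble(df)
  attr(out, "geometry") <- geometry
  class(out) <- c("fixation_df", class(out))
  out
}

#' Retrieve the display geometry attached to a fixation table
#' @param x A `fixation_df` (or any object with a `geometry` attribute).
#' @return The [display_geometry()].
#' @export
fx_geometry <- function(x) {
  g <- attr(x, "geometry", exact = TRUE)
  if (is.null(g)) stop("object carries no display geometry; ",
                       "construct it with fixation_data()", call. = FALSE)
  g
}

#' Subset a fixation table, keeping its geometry
#'
#' Thin wrapper around [dplyr::filter()] that re-attaches the geometry
#' attribute (ordinary dplyr verbs return a plain tibble).
#'
#' @param fixations A `fixation_df`.
#' @param ... Conditions passed to [dplyr::filter()].
#' @return A `fixation_df`.
#' @export
fx_filter <- function(fixations, ...) {
  g <- fx_geometry(fixations)
  new_fixation_df(dplyr::filter(tibble::as_tibble(fixations), ...), g)
}

#' Read and write fixation tables
#'
#' Delimited text with a header row and columns exactly
#' `subject,image,category,trial_index,x,y` (extra columns are preserved but
#' ignored). Comma and tab delimiters are auto-detected on read; writes are
#' CSV, UTF-8, in deterministic (subject, image, trial_index) order.
#'
#' @param path File path.
#' @param geometry A [display_geometry()].
#' @param oob Out-of-bounds policy, see [fixation_data()].
#' @param max_fixations See [fixation_data()].
#' @return `read_fixations()` returns a `fixation_df`; `write_fixations()`
#'   returns `path` invisibly.
#' @export
read_fixations <- function(path, geometry, oob = c("drop", "error"),
                           max_fixations = Inf) {
  if (!file.exists(path)) stop("fixation file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty fixation file: ", path, call. = FALSE)
  delim <- if (grepl("\t", first)) "\t" else ","
  # readr warns about parse problems; we inspect problems() and raise a
  # typed error ourselves, so the warning is redundant
  df <- suppressWarnings(readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      subject = readr::col_character(),
      image = readr::col_character(),
      category = readr::col_character(),
      trial_index = readr::col_double(),
      x = readr::col_double(),
      y = readr::col_double(),
      .default = readr::col_guess()
    )
  ))
  if (nrow(df) == 0) stop("fixation file has a header but no records: ",
                          path, call. = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("malformed fixation file (", nrow(prob), " parsing problem(s), ",
         "first at row ", prob$row[1], "): ", path, call. = FALSE)
  }
  fixation_data(df, geometry, oob = oob, max_fixations = max_fixations)
}

#' @rdname read_fixations
#' @param fixations A `fixation_df`.
#' @export
write_fixations <- function(fixations, path) {
  df <- tibble::as_tibble(fixations)
  df <- dplyr::arrange(df, .data$subject, .data$image, .data$trial_index)
  core <- c("subject", "image", "category", "trial_index", "x", "y")
  df <- dplyr::relocate(df, dplyr::all_of(core))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
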