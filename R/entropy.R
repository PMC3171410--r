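#' Binned samples for entropy estimation
#'
#' Entropy and KL estimators operate on histograms: a vector (or grid) of
#' non-negative integer counts over `N >= 2` bins with total `n >= 1`.
#'
#' @param counts Integer vector or matrix of bin counts.
#' @return A `binned_sample` list with `counts` (flattened), `n`, `n_bins`
#'   and the original dim.
#' @export
binned_sample <- function(counts) {
  v <- as.vector(counts)
  if (length(v) < 2) stop("need at least 2 bins", call. = FALSE)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(v)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  structure(list(counts = v, n = n, n_bins = length(v), dim = dim(counts)),
            class = "binned_sample")
}

as_binned <- function(x) if (inherits(x, "binned_sample")) x else binned_sample(x)

#' Entropy estimators for binned samples
#'
#' Plug-in (maximum-likelihood) entropy is negatively biased at small
#' sample sizes; these estimators reduce that bias:
#' \describe{
#'   \item{`ml`}{`-sum((c/n) * log(c/n))` over occupied bins;}
#'   \item{`miller_madow`}{ML plus the first-order correction
#'     `(m - 1) / (2n)`, `m` = occupied bins;}
#'   \item{`chao_shen`}{coverage-adjusted Horvitz-Thompson estimator:
#'     with coverage `C = 1 - f1/n` (`f1` = singleton bins) and
#'     `p_cs = C * c / n`, the estimate is
#'     `-sum(p_cs * log(p_cs) / (1 - (1 - p_cs)^n))`;}
#'   \item{`jeffreys`}{plug-in entropy of the Dirichlet(1/2)-smoothed
#'     frequencies `(c + 1/2) / (n + N/2)` over all bins.}
#' }
#'
#' @param sample A [binned_sample()] (or raw counts).
#' @param method One of `"ml"`, `"miller_madow"`, `"chao_shen"`,
#'   `"jeffreys"`.
#' @param log_base `exp(1)` for nats (default) or `2` for bits.
#' @return A one-row tibble: `value`, `method`, `log_base`, `n`, `n_bins`.
#'   Chao-Shen signals an error when every observation is a singleton
#'   (coverage 0) -- increase the sample size.
#' @export
entropy_estimate <- function(sample,
                             method = c("ml", "miller_madow", "chao_shen",
                                        "jeffreys"),
                             log_base = exp(1)) {
  s <- as_binned(sample)
  method <- match.arg(method)
  value <- switch(method,
    ml = h_ml(s$counts, s$n),
    miller_madow = h_ml(s$counts, s$n) + (sum(s$counts > 0) - 1) / (2 * s$n),
    chao_shen = h_chao_shen(s$counts, s$n),
    jeffreys = h_plugin((s$counts + 0.5) / (s$n + s$n_bins / 2))
  ) / log(log_base)
  tibble::tibble(value = value, method = method, log_base = log_base,
                 n = s$n, n_bins = s$n_bins)
}

h_ml <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

h_plugin <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

chao_shen_terms <- function(counts, n) {
  f1 <- sum(counts == 1)
  coverage <- 1 - f1 / n
  if (coverage <= 0) {
    stop("Chao-Shen coverage is zero (every observation is a singleton); ",
         "increase the sample size", call. = FALSE)
  }
  occ <- counts > 0
  p_cs <- coverage * counts[occ] / n
  list(p_cs = p_cs, weight = 1 - (1 - p_cs)^n, occupied = occ)
}

h_chao_shen <- function(counts, n) {
  ct <- chao_shen_terms(counts, n)
  -sum(ct$p_cs * log(ct$p_cs) / ct$weight)
}

#' Small-sample corrected KL divergence of a sample against a model density
#'
#' Estimates `KL(P || Q)` where `P` is known only through a binned sample
#' and `Q` is a model probability density over the same bins. The plug-in
#' (`ml`) estimate is positively biased at small `n`; `chao_shen` corrects
#' both the entropy and cross-entropy terms with the coverage-adjusted
#' probabilities (cross term `-sum(p_cs * log(q) / (1 - (1 - p_cs)^n))`),
#' and `jeffreys` applies Dirichlet(1/2) smoothing to the counts before the
#' plug-in divergence.
#'
#' @param sample A [binned_sample()] (or raw counts), shape-compatible
#'   with `q`.
#' @param q Model density: `density_map` or non-negative array summing
#'   to 1 with as many cells as the sample has bins.
#' @param method `"ml"`, `"chao_shen"` or `"jeffreys"`.
#' @inheritParams entropy_estimate
#' @param q_floor Floor applied to `q` (then renormalized) so occupied
#'   bins never divide by zero; default `1e-12` of uniform mass.
#' @return A one-row tibble: `value`, `method`, `log_base`, `n`, `n_bins`.
#' @export
kl_estimate <- function(sample, q, method = c("ml", "chao_shen", "jeffreys"),
                        log_base = exp(1), q_floor = NULL) {
  s <- as_binned(sample)
  method <- match.arg(method)
  qv <- as.vector(if (inherits(q, "salience_map")) unclass_map(q) else q)
  if (length(qv) != s$n_bins) {
    stop("model density has ", length(qv), " cells but the sample has ",
         s$n_bins, " bins", call. = FALSE)
  }
  if (is.null(q_floor)) q_floor <- 1e-12 / s$n_bins
  qv <- pmax(qv, q_floor)
  qv <- qv / sum(qv)
  value <- switch(method,
    ml = {
      occ <- s$counts > 0
      p <- s$counts[occ] / s$n
      sum(p * (log(p) - log(qv[occ])))
    },
    chao_shen = {
      ct <- chao_shen_terms(s$counts, s$n)
      sum(ct$p_cs * (log(ct$p_cs) - log(qv[ct$occupied])) / ct$weight)
    },
    jeffreys = {
      p <- (s$counts + 0.5) / (s$n + s$n_bins / 2)
      sum(p * (log(p) - log(qv)))
    }
  ) / log(log_base)
  tibble::tibble(value = value, method = method, log_base = log_base,
                 n = s$n, n_bins = s$n_bins)
}

#' Sample-size bias simulation for entropy / KL estimators
#'
#' Draws `reps` multinomial samples of each size in `n_grid` from a known
#' density and applies every requested estimator, returning per (method,
#' n) the mean and SD of the estimates. For `statistic = "kl"` the sample
#' is scored against the generating density itself, so the true value is 0
#' and the mean estimate is the estimator's bias; for
#' `statistic = "entropy"` the reference is the density's entropy.
#' Reproducible under `seed`. Replicates where Chao-Shen coverage is zero
#' (possible at very small `n`) are dropped for that method and counted in
#' `n_ok`.
#'
#' @param truth Generating density (`density_map` or unit-mass array).
#' @param methods Estimator names, see [entropy_estimate()] /
#'   [kl_estimate()].
#' @param n_grid Integer vector of sample sizes.
#' @param reps Replicates per size.
#' @param seed Integer seed.
#' @param statistic `"kl"` (against `truth`) or `"entropy"`.
#' @inheritParams entropy_estimate
#' @return A tibble: `method`, `n`, `mean`, `sd`, `n_ok`, plus
#'   `true_value` (0 for KL, the density entropy for entropy).
#' @export
bias_simulation <- function(truth, methods = c("ml", "chao_shen", "jeffreys"),
                            n_grid, reps = 200, seed = 1,
                            statistic = c("kl", "entropy"),
                            log_base = exp(1)) {
  statistic <- match.arg(statistic)
  tv <- as.vector(if (inherits(truth, "salience_map")) unclass_map(truth) else truth)
  stopifnot(all(tv >= 0), abs(sum(tv) - 1) < 1e-6, reps >= 1)
  tv <- tv / sum(tv)
  if (statistic == "entropy") {
    allowed <- c("ml", "miller_madow", "chao_shen", "jeffreys")
  } else {
    allowed <- c("ml", "chao_shen", "jeffreys")
  }
  methods <- match.arg(methods, allowed, several.ok = TRUE)
  true_value <- if (statistic == "kl") 0 else h_plugin(tv) / log(log_base)
  set.seed(seed)
  out <- vector("list", length(n_grid))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    cnts <- stats::rmultinom(reps, n, tv)
    est <- lapply(methods, function(m) {
      vals <- apply(cnts, 2, function(cc) {
        tryCatch(
          if (statistic == "kl") {
            kl_estimate(binned_sample(cc), tv, method = m,
                        log_base = log_base)$value
          } else {
            entropy_estimate(binned_sample(cc), method = m,
                             log_base = log_base)$value
          },
          error = function(e) NA_real_
        )
      })
      tibble::tibble(
        method = m, n = n,
        mean = mean(vals, na.rm = TRUE),
        sd = stats::sd(vals, na.rm = TRUE),
        n_ok = sum(!is.na(vals)),
        true_value = true_value
      )
    })
    out[[i]] <- dplyr::bind_rows(est)
  }
  dplyr::bind_rows(out)
}

#' Coarse analysis grid for KL work
#'
#' KL divergence on the full pixel grid is dominated by sampling noise;
#' the package's convention is a coarse grid whose bin area equals the
#' area of a disc of `diameter_deg` degrees of visual angle (2 degrees,
#' the effective FDM resolution, by default). On a 1280 x 960 screen of
#' 28.4 x 21.3 degrees this yields 16 x 12 bins (N = 192).
#'
#' @param geometry A [display_geometry()].
#' @param diameter_deg Disc diameter in degrees.
#' @return Integer vector `c(rows, cols)`.
#' @export
coarse_grid <- function(geometry, diameter_deg = 2) {
  bin_area_px <- pi * (diameter_deg / 2)^2 *
    geometry$px_per_deg_x * geometry$px_per_deg_y
  n_bins <- geometry$width_px * geometry$height_px / bin_area_px
  aspect <- geometry$width_px / geometry$height_px
  cols <- max(2L, round(sqrt(n_bins * aspect)))
  rows <- max(2L, round(n_bins / cols))
  c(rows, cols)
}
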