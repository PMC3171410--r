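test_that("evaluate_prediction dispatches and respects AUC identities", {
  g <- tiny_geom()
  u <- density_map(matrix(1 / (48 * 64), 48, 64), g)
  fx <- fix_df(g, x = runif(20, 0, 64), y = runif(20, 0, 48))
  expect_identical(evaluate_prediction(u, fx, "auc")$value, 0.5)
  # duplicated test fixations leave the AUC unchanged (linearity)
  set.seed(23)
  m <- as_density_map(salience_map(matrix(runif(48 * 64), 48, 64), g))
  dup <- fixation_data(dplyr::bind_rows(fx, fx), g, max_fixations = Inf)
  expect_equal(evaluate_prediction(m, fx, "auc")$value,
               evaluate_prediction(m, dup, "auc")$value, tolerance = 1e-12)
})

test_that("self-prediction AUC approaches the theoretical ceiling", {
  g <- tiny_geom()
  set.seed(24)
  v <- unclass(fdm(central_dataset(g, 2, 2, per = 40, seed = 25), scale = 1 / 4))
  p <- density_map(v[, ], g, scale = 1 / 4)
  # draw test fixations from p itself, at cell centres
  n <- 4000
  cells <- sample(length(v), n, replace = TRUE, prob = as.vector(v))
  row <- (cells - 1) %% nrow(v) + 1; col <- (cells - 1) %/% nrow(v) + 1
  fx <- fix_df(g, x = (col - 0.5) * 4, y = (row - 0.5) * 4)
  got <- evaluate_prediction(p, fx, "auc")$value
  expect_equal(got, theoretical_max_auc(p), tolerance = 0.02)
  expect_lt(theoretical_max_auc(p), 1)
})

test_that("lower bound with maximal training sets equals the direct pooled evaluation", {
  g <- tiny_geom()
  ds <- central_dataset(g, n_subjects = 3, n_images = 3, per = 6, seed = 51)
  sch <- cv_schedule(subject_sizes = 2, image_sizes = 2, reps = 1)
  lb <- lower_bound(ds, sch, scale = 1 / 4, seed = 99)
  expect_equal(nrow(lb), 1)

  # oracle: for every test trial the training set is forced to be the full
  # complement, so the prediction is the plain spatial bias excluding the
  # test subject and image
  scores <- c()
  for (s in unique(ds$subject)) for (i in unique(ds$image)) {
    pred <- spatial_bias(ds, subjects = setdiff(unique(ds$subject), s),
                         images = setdiff(unique(ds$image), i), scale = 1 / 4)
    test <- fx_filter(ds, subject == s, image == i)
    scores <- c(scores, evaluate_prediction(pred, test, "auc")$value)
  }
  expect_equal(lb$mean, mean(scores), tolerance = 1e-10)
  expect_equal(lb$n_tests, 9)

  # seeded reruns are identical
  lb2 <- lower_bound(ds, sch, scale = 1 / 4, seed = 99)
  expect_identical(tidy(lb), tidy(lb2))
})

test_that("infeasible schedule cells are omitted", {
  g <- tiny_geom()
  ds <- central_dataset(g, n_subjects = 3, n_images = 3, per = 5, seed = 52)
  sch <- cv_schedule(subject_sizes = c(1, 2, 10), image_sizes = c(1, 8),
                     reps = 1)
  lb <- lower_bound(ds, sch, scale = 1 / 4, seed = 1)
  expect_setequal(unique(lb$n_subjects), c(1, 2))
  expect_setequal(unique(lb$n_images), 1)
})

test_that("train/test hygiene: held-out subjects and images never leak", {
  g <- tiny_geom()
  # each subject owns one distinct corner cell; prediction for a test
  # subject can place no mass there, so its fixations score at the map
  # minimum and AUC falls below chance
  pos <- list(c(4, 4), c(60, 4), c(4, 44), c(60, 44))
  df <- dplyr::bind_rows(lapply(1:4, function(s) {
    tibble::tibble(subject = paste0("s", s), image = rep(c("i1", "i2"), each = 5),
                   category = "free", trial_index = rep(1:5, 2),
                   x = pos[[s]][1], y = pos[[s]][2])
  }))
  ds <- fixation_data(df, g, max_fixations = Inf)
  ub <- upper_bound(ds, train_sizes = 3, reps = 1,
                    smoothing = smoothing_spec(0.5), scale = 1 / 4, seed = 1)
  expect_lt(ub$mean, 0.5)

  # lower bound: the test image's hotspot must not leak either; with
  # image-specific locations and one training image the prediction misses
  # the test image's location entirely
  df2 <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(subject = rep(paste0("s", 1:3), each = 5),
                   image = paste0("i", i), category = "free",
                   trial_index = rep(1:5, 3),
                   x = c(10, 32, 54)[i], y = c(10, 24, 38)[i])
  }))
  ds2 <- fixation_data(df2, g, max_fixations = Inf)
  lb <- lower_bound(ds2, cv_schedule(subject_sizes = 2, image_sizes = 2,
                                     reps = 1),
                    smoothing = smoothing_spec(0.5), scale = 1 / 4, seed = 2)
  expect_lt(lb$mean, 0.5)
})

test_that("the subject-specific bias helps subjects with strong idiosyncrasy", {
  cfg <- synthetic_config(
    n_subjects = 8, n_images = 10, mixture_weights = c(0.35, 0.15, 0.5),
    subject_weight_sd = 3,
    categories = list(free = list(center = c(0.5, 0.5), sd_deg = c(4, 3))),
    seed = 61
  )
  ds <- make_dataset(cfg)
  sch <- cv_schedule(subject_sizes = 1, image_sizes = 4, reps = 3,
                     reps_subject_specific = 3)
  own <- subject_bias_eval(ds$fixations, sch, image_sizes = 4,
                           scale = 1 / 16, seed = 3)
  foreign <- lower_bound(ds$fixations, sch, scale = 1 / 16, seed = 3)
  expect_gt(own$mean, foreign$mean)
})

test_that("PCA of subject biases has sorted spectra and exact reconstructions", {
  g <- tiny_geom()
  # two archetype groups of subjects: left-lookers and right-lookers
  mk <- function(s, cx) {
    set.seed(100 + s)
    tibble::tibble(subject = sprintf("s%02d", s),
                   image = rep(sprintf("i%02d", 1:4), each = 10),
                   category = "free", trial_index = rep(1:10, 4),
                   x = pmin(pmax(rnorm(40, cx, 6), 0), 63.9),
                   y = pmin(pmax(rnorm(40, 24, 6), 0), 47.9))
  }
  df <- dplyr::bind_rows(lapply(1:8, function(s) mk(s, if (s <= 4) 18 else 46)))
  ds <- fixation_data(df, g, max_fixations = Inf)
  basis <- pca_basis(ds, subjects = sprintf("s%02d", 1:8),
                     images = sprintf("i%02d", 1:4), k = 3, scale = 1 / 4)
  expect_true(all(diff(basis$eigenvalues) <= 1e-12))
  expect_equal(crossprod(basis$components), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_gt(tidy(basis)$prop_variance[1], 0.7) # the archetype axis dominates
  expect_error(pca_basis(ds, subjects = sprintf("s%02d", 1:3),
                         images = sprintf("i%02d", 1:4), k = 5), "k \\+ 1")

  # reconstruction identities
  mean_dm <- density_map(basis$mean_map / sum(basis$mean_map), g, scale = 1 / 4)
  expect_equal(unclass(pca_clean_bias(basis, mean_dm)),
               basis$mean_map / sum(basis$mean_map), tolerance = 1e-8,
               ignore_attr = TRUE)

  # a bias lying exactly in span(mean, components) comes back unchanged
  w <- c(0.004, -0.002, 0.001)
  v <- as.vector(basis$mean_map) + basis$components %*% w
  while (any(v < 0)) { # shrink until the span point is a valid density
    w <- w / 2
    v <- as.vector(basis$mean_map) + basis$components %*% w
  }
  in_span <- density_map(matrix(v / sum(v), 12, 16), g, scale = 1 / 4)
  # nb: pca_clean_bias regresses the *centred* map; the unit-mass rescale of
  # v keeps it in the affine span because components are orthogonal to 1
  expect_equal(unclass(pca_clean_bias(basis, in_span)), unclass(in_span)[, ],
               tolerance = 1e-6, ignore_attr = TRUE)

  # residual of the regression is orthogonal to every component
  set.seed(71)
  noisy <- matrix(runif(12 * 16), 12, 16); noisy <- noisy / sum(noisy)
  wfit <- crossprod(basis$components, as.vector(noisy) - as.vector(basis$mean_map))
  resid <- (as.vector(noisy) - as.vector(basis$mean_map)) -
    basis$components %*% wfit
  expect_equal(as.vector(crossprod(basis$components, resid)), rep(0, 3),
               tolerance = 1e-10)
})

test_that("eigen-weighted and combined predictions honour their identities", {
  g <- tiny_geom()
  # identical subjects: centred variance is ~0 and the eigen-weighted map
  # equals the mean map
  df <- dplyr::bind_rows(lapply(1:4, function(s) {
    tibble::tibble(subject = paste0("s", s),
                   image = rep(c("i1", "i2"), each = 6), category = "free",
                   trial_index = rep(1:6, 2),
                   x = rep(c(20, 30, 40), 4), y = rep(c(12, 24, 36), 4))
  }))
  ds <- fixation_data(df, g, max_fixations = Inf)
  basis <- pca_basis(ds, subjects = paste0("s", 1:4), images = c("i1", "i2"),
                     k = 2, scale = 1 / 4)
  expect_lt(basis$eigenvalues[1], 1e-12)
  ew <- eigen_weighted_bias(basis)
  expect_equal(unclass(ew), basis$mean_map / sum(basis$mean_map),
               tolerance = 1e-6, ignore_attr = TRUE)

  set.seed(81)
  inter <- as_density_map(salience_map(matrix(runif(12 * 16) + 0.1, 12, 16), g))
  bias <- as_density_map(salience_map(matrix(runif(12 * 16) + 0.1, 12, 16), g))
  u <- density_map(matrix(1 / 192, 12, 16), g)
  expect_equal(unclass(combined_prediction(inter, bias, bias)),
               unclass(inter)[, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(combined_prediction(inter, u, u)),
               unclass(inter)[, ], tolerance = 1e-12, ignore_attr = TRUE)
  g2 <- display_geometry(8, 6, 8, 6)
  expect_error(combined_prediction(inter, bias,
                                   density_map(matrix(1 / 48, 6, 8), g2)),
               "grid")
  out <- combined_prediction(inter, bias, u)
  expect_s3_class(out, "density_map")
  expect_equal(sum(out), 1, tolerance = 1e-12)
})
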