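test_that("sample_scores implements the three negative strategies", {
  g <- display_geometry(2, 2, 2, 2)
  m <- salience_map(matrix(c(4, 3, 2, 1), 2, 2), g)
  fx <- fix_df(g, x = 0.5, y = 0.5) # cell (1,1), value 4
  s_all <- sample_scores(m, fx, "all_pixels")
  expect_equal(s_all$positives, 4)
  expect_equal(sort(s_all$negatives), 1:4)
  s_non <- sample_scores(m, fx, "nonfixated_pixels")
  expect_equal(sort(s_non$negatives), 1:3)
  donors <- tibble::tibble(x = rep(1.5, 10), y = rep(0.5, 10)) # cell (1,2), value 2
  s_don <- sample_scores(m, fx, "other_image_fixations", donors = donors)
  expect_equal(s_don$negatives, rep(2, 10))
  expect_error(sample_scores(m, fx, "other_image_fixations"), "donor")
})

test_that("AUC handles the canonical cases exactly", {
  expect_identical(auc_score(c(5, 5, 5), c(5, 5)), 0.5) # all ties: chance
  expect_identical(auc_score(c(3, 4), c(1, 2)), 1) # perfect separation
  expect_equal(auc_score(c(0.9, 0.7), c(0.8, 0.2, 0.1)), 5 / 6,
               tolerance = 1e-15)
  expect_error(auc_score(numeric(0), 1), "non-empty")
  expect_error(auc_score(c(1, NA), 1), "finite")
})

test_that("efficient AUC, trapezoidal ROC area and the pairwise statistic agree", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_tied_sample(80)
    a <- auc_score(s$positives, s$negatives)
    expect_equal(a, auc_pairwise(s$positives, s$negatives), tolerance = 1e-13)
    expect_equal(a, roc_auc(roc_curve(s$positives, s$negatives)),
                 tolerance = 1e-13)
  }
})

test_that("ROC curves are monotone and pass through the expected corners", {
  r <- roc_curve(c(2, 3), c(0, 1))
  expect_true(any(r$tpr == 1 & r$fpr == 0)) # perfect separation corner
  r2 <- roc_curve(2, 1)
  expect_equal(r2$tpr, c(0, 1, 1))
  expect_equal(r2$fpr, c(0, 0, 1))
  set.seed(7)
  s <- random_tied_sample(60)
  r3 <- roc_curve(s$positives, s$negatives)
  expect_true(all(diff(r3$tpr) >= 0) && all(diff(r3$fpr) >= 0))
  expect_equal(r3$tpr[nrow(r3)], 1)
  expect_equal(r3$fpr[nrow(r3)], 1)
})

test_that("AUC is linear under partition of the positives", {
  set.seed(55)
  for (i in 1:100) {
    neg <- runif(sample(5:50, 1))
    pos <- round(runif(sample(4:40, 1)), 2)
    k <- sample(2:3, 1)
    grp <- sample(rep_len(1:k, length(pos)))
    whole <- auc_score(pos, neg)
    parts <- vapply(1:k, function(j) {
      if (sum(grp == j) == 0) return(NA_real_)
      auc_score(pos[grp == j], neg)
    }, numeric(1))
    w <- tabulate(grp, k) / length(pos)
    expect_equal(whole, sum(w * parts, na.rm = TRUE), tolerance = 1e-10)
  }
})

test_that("NSS matches direct arithmetic and decomposes linearly", {
  g <- display_geometry(2, 2, 2, 2)
  m <- salience_map(matrix(c(1, 2, 3, 6), 2, 2), g) # pop SD = sqrt(3.5)
  fx6 <- fix_df(g, x = 1.5, y = 1.5) # cell (2,2) value 6
  expect_equal(nss_score(m, fx6), 3 / sqrt(3.5), tolerance = 1e-12)
  fx3 <- fix_df(g, x = 1.5, y = 0.5) # value 3 = map mean
  expect_equal(nss_score(m, fx3), 0, tolerance = 1e-12)
  fx_dup <- fix_df(g, x = rep(1.5, 4), y = rep(1.5, 4))
  expect_equal(nss_score(m, fx_dup), nss_score(m, fx6))
  expect_error(nss_score(salience_map(matrix(1, 2, 2), g), fx6), "constant")

  # weighted decomposition over subject groups, exact
  ga <- tiny_geom()
  set.seed(12)
  mm <- salience_map(matrix(runif(48 * 64), 48, 64), ga)
  xa <- runif(30, 0, 64); ya <- runif(30, 0, 48)
  xb <- runif(12, 0, 64); yb <- runif(12, 0, 48)
  joint <- nss_score(mm, tibble::tibble(x = c(xa, xb), y = c(ya, yb)))
  parts <- (30 * nss_score(mm, tibble::tibble(x = xa, y = ya)) +
            12 * nss_score(mm, tibble::tibble(x = xb, y = yb))) / 42
  expect_equal(joint, parts, tolerance = 1e-12)
})

test_that("chance-adjusted salience is the mean difference", {
  g <- display_geometry(2, 1, 2, 1)
  m <- salience_map(matrix(c(0, 10), 1, 2), g)
  fx <- fix_df(g, x = c(1.5, 1.2), y = c(0.5, 0.5)) # both on the 10-cell
  expect_equal(cas_score(m, fx), 5)
  expect_equal(cas_score(salience_map(matrix(7, 1, 2), g), fx), 0)
  # fixations covering every cell once
  fx_all <- fix_df(g, x = c(0.5, 1.5), y = c(0.5, 0.5))
  expect_equal(cas_score(m, fx_all), 0)
})

test_that("ratio of medians matches a brute-force disc scan", {
  g <- display_geometry(10, 10, 10, 10) # 1 px per degree
  expect_equal(rom_score(salience_map(matrix(3, 10, 10), g),
                         fix_df(g, x = c(2, 7), y = c(3, 8)), seed = 1), 1)
  # radius covering the whole image: both medians are the global max
  set.seed(8)
  m <- salience_map(matrix(runif(100), 10, 10), g)
  expect_equal(rom_score(m, fix_df(g, x = c(2, 7), y = c(3, 8)),
                         radius_deg = 30, seed = 2), 1)

  # single-peak map, fixations on the peak, fixed seed, vs exhaustive scan
  v <- matrix(0.1, 10, 10); v[4, 6] <- 5
  mp <- salience_map(v, g)
  fx <- fix_df(g, x = c(5.5, 5.2, 5.8), y = c(3.5, 3.1, 3.9)) # peak cell
  r_deg <- 2.2
  got <- rom_score(mp, fx, radius_deg = r_deg, n_controls = 50, seed = 42)
  # oracle: same control draw, independent full scan of the ellipse
  set.seed(42)
  cx <- runif(50, 0, 10) * (1 - 1e-12); cy <- runif(50, 0, 10) * (1 - 1e-12)
  scan_max <- function(px, py) {
    col <- floor(px) + 1; row <- floor(py) + 1
    best <- -Inf
    for (r in 1:10) for (cc in 1:10) {
      if ((r - row)^2 / r_deg^2 + (cc - col)^2 / r_deg^2 <= 1) {
        best <- max(best, v[r, cc])
      }
    }
    best
  }
  o_fix <- median(mapply(scan_max, fx$x, fx$y))
  o_ctl <- median(mapply(scan_max, cx, cy))
  expect_equal(got, o_fix / o_ctl, tolerance = 1e-12)
})

test_that("percentile measure counts hits in the top-value area", {
  g <- display_geometry(10, 1, 10, 1)
  m <- salience_map(matrix(1:10, 1, 10), g)
  # cells 9 and 3: value 9 is in the top 20% (threshold = 9), value 3 is not
  fx <- fix_df(g, x = c(8.5, 2.5), y = c(0.5, 0.5))
  expect_equal(percentile_score(m, fx, 80), 0.5)
  fx_max <- fix_df(g, x = rep(9.5, 3), y = rep(0.5, 3))
  expect_equal(percentile_score(m, fx_max, 80), 1)
  expect_error(percentile_score(m, fx, 0), "percentile")
})

test_that("naive Bayes percent correct behaves at the extremes and on a tiny oracle", {
  # perfectly separated score distributions
  s_sep <- list(positives = runif(50, 10, 11), negatives = runif(50, 0, 1))
  expect_equal(nb_percent_correct(s_sep, seed = 1), 1)

  # identical distributions, balanced classes: chance
  set.seed(60)
  s_id <- list(positives = rnorm(1000), negatives = rnorm(1000))
  expect_equal(nb_percent_correct(s_id, seed = 2), 0.5, tolerance = 0.05)

  # 4 + 4 points, 2 bins, 2 folds: replicate fold-by-fold by hand
  pos <- c(0.9, 0.8, 0.2, 0.7); neg <- c(0.1, 0.3, 0.6, 0.25)
  got <- nb_percent_correct(list(positives = pos, negatives = neg),
                            n_bins = 2, k_folds = 2, seed = 7)
  edges <- seq(min(c(pos, neg)), max(c(pos, neg)), length.out = 3)
  bin <- function(v) pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1), 2)
  set.seed(7)
  fp <- sample(rep_len(1:2, 4)); fn <- sample(rep_len(1:2, 4))
  correct <- 0
  for (f in 1:2) {
    hp <- tabulate(bin(pos)[fp != f], 2) + 1
    hn <- tabulate(bin(neg)[fn != f], 2) + 1
    rule <- (hp / sum(hp)) > (hn / sum(hn))
    correct <- correct + sum(rule[bin(pos)[fp == f]]) +
      sum(!rule[bin(neg)[fn == f]])
  }
  expect_equal(got, correct / 8)
  expect_error(nb_percent_correct(list(positives = 1:3, negatives = 1:20)),
               "k_folds")
})

test_that("KL divergence matches closed forms and floors zero predictions", {
  g <- display_geometry(2, 1, 2, 1)
  p <- density_map(matrix(c(0.5, 0.5), 1, 2), g)
  q <- density_map(matrix(c(0.25, 0.75), 1, 2), g)
  expect_equal(kl_div(p, q), 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl_div(p, q, log_base = 2),
               (0.5 * log(2) + 0.5 * log(2 / 3)) / log(2), tolerance = 1e-12)
  pd <- density_map(matrix(c(1, 0), 1, 2), g)
  u <- density_map(matrix(c(0.5, 0.5), 1, 2), g)
  expect_equal(kl_div(pd, u), log(2), tolerance = 1e-12)
  # q = 0 where p > 0 stays finite thanks to the floor
  expect_true(is.finite(kl_div(u, pd)))
  expect_error(kl_div(p, density_map(matrix(rep(0.25, 4), 2, 2),
                                     display_geometry(2, 2, 2, 2))), "shape")
})

test_that("symmetric KL is symmetric and sums both directions", {
  g <- display_geometry(2, 1, 2, 1)
  p <- density_map(matrix(c(0.5, 0.5), 1, 2), g)
  q <- density_map(matrix(c(0.25, 0.75), 1, 2), g)
  expect_equal(symmetric_kl(p, q), kl_div(p, q) + kl_div(q, p))
  expect_identical(symmetric_kl(p, q), symmetric_kl(q, p))
  expect_equal(symmetric_kl(p, p), 0)
})

test_that("map correlation matches the textbook sum formula", {
  g <- tiny_geom()
  set.seed(77)
  pv <- matrix(runif(48 * 64), 48, 64); pv <- pv / sum(pv)
  p <- density_map(pv, g)
  expect_equal(map_correlation(p, salience_map(2 * pv + 1, g)), 1,
               tolerance = 1e-12)
  expect_equal(map_correlation(p, salience_map(-pv, g)), -1, tolerance = 1e-12)
  qv <- matrix(runif(48 * 64), 48, 64)
  a <- as.vector(pv); b <- as.vector(qv)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(map_correlation(p, salience_map(qv, g)), r_manual,
               tolerance = 1e-12)
  expect_error(map_correlation(p, salience_map(matrix(1, 48, 64), g)),
               "constant")
})

test_that("the theoretical AUC ceiling equals the weighted pairwise oracle", {
  g <- display_geometry(10, 10, 10, 10)
  oracle <- function(p) {
    n <- length(p); s <- 0
    for (i in seq_len(n)) {
      s <- s + p[i] * sum((p[i] > p) + 0.5 * (p[i] == p)) / n
    }
    s
  }
  expect_equal(theoretical_max_auc(matrix(0.01, 10, 10)), 0.5)
  delta <- matrix(0, 10, 10); delta[3, 7] <- 1
  expect_equal(theoretical_max_auc(delta), 1 - 1 / 200, tolerance = 1e-14)
  set.seed(90)
  for (i in 1:20) {
    n <- sample(4:100, 1)
    p <- runif(n); p[sample(n, n %/% 4)] <- p[1] # inject ties
    p <- p / sum(p)
    expect_equal(theoretical_max_auc(matrix(p, 1, n)), oracle(p),
                 tolerance = 1e-12)
    expect_lt(theoretical_max_auc(matrix(p, 1, n)), 1)
  }
})

test_that("rank measures are invariant to monotone transforms, value measures are not", {
  g <- tiny_geom()
  set.seed(33)
  v <- matrix(runif(48 * 64), 48, 64)
  m <- salience_map(v, g)
  m_exp <- salience_map(exp(3 * v), g)
  fx <- fix_df(g, x = runif(20, 0, 64), y = runif(20, 0, 48))
  s1 <- sample_scores(m, fx); s2 <- sample_scores(m_exp, fx)
  expect_equal(auc_score(s1$positives, s1$negatives),
               auc_score(s2$positives, s2$negatives), tolerance = 1e-12)
  expect_equal(percentile_score(m, fx), percentile_score(m_exp, fx))
  expect_false(isTRUE(all.equal(nss_score(m, fx), nss_score(m_exp, fx))))
  p <- as_density_map(m)
  expect_false(isTRUE(all.equal(
    kl_div(p, as_density_map(m)), kl_div(p, as_density_map(m_exp)))))
  expect_false(isTRUE(all.equal(
    map_correlation(p, m), map_correlation(p, m_exp))))
})

test_that("evaluate_map returns tidy one-row results for every measure", {
  g <- tiny_geom()
  set.seed(13)
  m <- salience_map(matrix(runif(48 * 64), 48, 64), g)
  fx <- fix_df(g, x = runif(30, 0, 64), y = runif(30, 0, 48))
  for (meas in c("auc", "nss", "cas", "percentile", "kl", "skl", "corr",
                 "max_auc")) {
    r <- evaluate_map(fx, m, measure = meas)
    expect_identical(nrow(r), 1L)
    expect_identical(r$measure, meas)
    expect_true(is.finite(r$value))
    expect_identical(r$n_pos, 30L)
  }
  r_rom <- evaluate_map(fx, m, measure = "rom", seed = 5)
  expect_true(r_rom$value > 0)
  r_nb <- evaluate_map(fx, m, measure = "nb", seed = 5, k_folds = 5)
  expect_true(r_nb$value >= 0 && r_nb$value <= 1)
})
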