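# The statistical toolkit.

test_that("accuracy tables apply the exclusion rules", {
  # 10 trials, 7 correct, nothing excluded
  tt <- make_trials("a", c(rep(TRUE, 7), rep(FALSE, 3)))
  at <- accuracy_table(tt, "p")
  expect_equal(at$pairs$accuracy, 0.7)
  expect_equal(at$pairs$n, 10)

  # correction trials never count
  tt2 <- rbind(tt, make_trials("a", rep(TRUE, 5), is_correction = TRUE))
  expect_equal(accuracy_table(tt2, "p")$pairs$accuracy, 0.7)

  # a session whose base-pair accuracy is 0.60 is dropped entirely
  good <- rbind(make_trials("old", rep(TRUE, 10), is_old = TRUE,
                            session = 1),
                make_trials("a", rep(TRUE, 10), session = 1))
  bad <- rbind(make_trials("old", c(rep(TRUE, 6), rep(FALSE, 4)),
                           is_old = TRUE, session = 2),
               make_trials("a", rep(FALSE, 10), session = 2))
  at3 <- accuracy_table(rbind(good, bad), "p")
  expect_equal(length(at3$excluded_sessions), 1L)
  expect_equal(at3$pairs$accuracy, 1)
  # at the threshold itself the session is kept
  edge <- rbind(make_trials("old", c(rep(TRUE, 13), rep(FALSE, 7)),
                            is_old = TRUE, session = 3),
                make_trials("a", rep(TRUE, 4), session = 3))
  expect_equal(length(accuracy_table(rbind(good, edge),
                                     "p")$excluded_sessions), 0L)

  # all-correction table degenerates with a flag
  allc <- make_trials("a", rep(TRUE, 5), is_correction = TRUE)
  expect_true(accuracy_table(allc, "p")$degenerate)
  expect_error(accuracy_table(tt, "missing"), "not present")

  # invariance to trial order
  perm <- tt[sample(nrow(tt)), ]
  expect_equal(accuracy_table(perm, "p")$pairs, at$pairs)
})

test_that("the exact binomial chance test matches closed forms", {
  b <- binomial_chance_test(20, 20)
  expect_equal(b$p_value, 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(binomial_chance_test(10, 20)$p_value, 1)
  # Clopper-Pearson interval brackets the estimate
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:50, 1); k <- sample(0:n, 1)
    b <- binomial_chance_test(k, n)
    expect_lte(b$ci[1], k / n)
    expect_gte(b$ci[2], k / n)
  }
  expect_error(binomial_chance_test(5, 4))
})

test_that("layer correlation profiles recover perfect and null structure", {
  set.seed(9)
  s <- matrix(rnorm(60 * 13), 60, 13,
              dimnames = list(NULL, paste0("L", 1:13)))
  prof <- layer_correlation_profile(s[, 4], s, n_perm = 200, seed = 1)
  expect_equal(prof$r[4], 1)
  expect_lte(prof$p_value[4], 1 / 201 + 1e-12)
  expect_true(all(prof$p_value > 0 & prof$p_value <= 1))

  # permuting both vectors identically leaves r unchanged
  p <- sample(60)
  prof2 <- layer_correlation_profile(s[p, 4], s[p, ], n_perm = 50, seed = 1)
  expect_equal(prof2$r, prof$r)

  # reproducibility under a fixed seed
  y <- rnorm(60)
  a <- layer_correlation_profile(y, s, n_perm = 100, seed = 7)
  b <- layer_correlation_profile(y, s, n_perm = 100, seed = 7)
  expect_identical(a$p_value, b$p_value)
  expect_error(layer_correlation_profile(1:5, s[1:4, ]), "length")
})

test_that("permutation p-values are uniform-ish under independence", {
  set.seed(31)
  s <- matrix(rnorm(80 * 13), 80, 13)
  ps <- replicate(30, layer_correlation_profile(
    rnorm(80), s, n_perm = 60)$p_value[1])
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("split-half reliability separates deterministic from guessing
           observers", {
  # deterministic observer: every pair all-correct or all-incorrect
  det <- do.call(rbind, lapply(1:12, function(i)
    make_trials(paste0("p", i), rep(i %% 2 == 0, 20))))
  r <- split_half_reliability(det, n_splits = 10, seed = 1)
  expect_equal(r$split_half_r, 1)
  expect_equal(r$full_set_r, 1)

  # pure guessing: correlation near zero
  set.seed(12)
  guess <- do.call(rbind, lapply(1:60, function(i)
    make_trials(paste0("p", i), runif(40) < 0.5)))
  rg <- split_half_reliability(guess, n_splits = 50, seed = 2)
  expect_lt(abs(rg$split_half_r), 0.15)

  # reliability grows with the number of trials per pair (simulated from
  # the same per-pair probabilities)
  set.seed(13)
  probs <- 0.5 + 0.4 * (1:40 / 40)
  tab_with <- function(m) do.call(rbind, lapply(1:40, function(i)
    make_trials(paste0("p", i), runif(m) < probs[i])))
  r_small <- split_half_reliability(tab_with(8), n_splits = 200, seed = 3)
  r_large <- split_half_reliability(tab_with(80), n_splits = 200, seed = 4)
  expect_gt(r_large$split_half_r, r_small$split_half_r)

  expect_error(split_half_reliability(make_trials("a", c(TRUE, TRUE))),
               "pairs")
})

test_that("Spearman-Brown fixes 0 and 1, hits the printed values, and is
           monotone", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(round(spearman_brown(0.46), 2), 0.63)
  expect_equal(round(spearman_brown(0.40), 2), 0.57)
  grid <- seq(-0.9, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(grid)) > 0))
  expect_error(spearman_brown(-1))
})

test_that("combined reliability is the geometric mean of the full-set
           reliabilities", {
  expect_equal(round(combined_reliability(spearman_brown(0.40),
                                          spearman_brown(0.46)), 2), 0.60)
  expect_equal(combined_reliability(0.7, 0.7), 0.7)
  expect_equal(combined_reliability(0, 0.9), 0)
  expect_error(combined_reliability(-0.1, 0.5))
})

test_that("the layer regression recovers exact and null fits", {
  set.seed(17)
  X <- matrix(rnorm(60 * 13), 60, 13,
              dimnames = list(NULL, paste0("L", 1:13)))
  fit <- suppressWarnings(layer_regression(X[, 7], X))  # exact fit warns
  expect_equal(fit$r_squared, 1)

  # response orthogonal to all regressors by construction
  y <- rnorm(60)
  resid <- stats::residuals(stats::lm(y ~ X))
  fit0 <- layer_regression(resid, X)
  expect_lt(fit0$r_squared, 1e-20)

  expect_equal(round(sqrt(0.10), 2), 0.32)
  f <- layer_regression(X[, 1] + rnorm(60), X)
  expect_equal(f$correlation_scale, sqrt(f$r_squared))
  expect_equal(nrow(f$coefficients), 13L)
})

test_that("the brightness predictor matches direct arithmetic and its
           invariances", {
  bt <- matrix(0.6, 10, 10); bd <- matrix(0.8, 10, 10)
  t1 <- matrix(0.5, 10, 10); d1 <- matrix(0.55, 10, 10)
  bp <- brightness_predictor(bt, bd, list(bt, t1), list(bd, d1))
  expect_equal(bp$values[1], 0)              # the base pair itself
  expect_equal(bp$values[2], (0.6 - 0.8) - (0.5 - 0.55))
  # uniform offset invariance
  off <- 0.05
  bp2 <- brightness_predictor(bt + off, bd + off,
                              list(bt + off, t1 + off),
                              list(bd + off, d1 + off))
  expect_equal(bp2$values, bp$values)
})

test_that("the pixel-similarity predictor matches hand arithmetic", {
  set.seed(2)
  bt <- matrix(runif(64), 8); bd <- matrix(runif(64), 8)
  t1 <- matrix(runif(64), 8); d1 <- matrix(runif(64), 8)
  ps <- pixel_similarity_predictor(bt, bd, list(t1), list(d1))
  co <- function(a, b) cor(as.vector(a), as.vector(b))
  manual <- (co(bt, d1) + co(bd, t1)) / 2 - (co(bd, d1) + co(bt, t1)) / 2
  expect_equal(ps$values[1], manual)

  # the base pair substituted as test pair gives sim(baseT, baseD) - 1 <= 0
  self <- pixel_similarity_predictor(bt, bd, list(bt), list(bd))
  expect_equal(self$values[1], co(bt, bd) - 1)
  expect_lte(self$values[1], 0)

  # constant similarity measure collapses to zero
  ps0 <- pixel_similarity_predictor(bt, bd, list(t1), list(d1),
                                    sim = function(a, b) 0.42)
  expect_equal(ps0$values[1], 0)

  expect_error(pixel_similarity_predictor(bt, bd, list(matrix(0, 4, 4)),
                                          list(d1)))
})

test_that("species comparison handles equal and degenerate groups", {
  tr <- function(subject, train_acc, test_acc, zvh, hvz) {
    rbind(make_trials("b", runif(40) < train_acc, subject = subject,
                      protocol = "training"),
          make_trials("t", runif(40) < test_acc, subject = subject,
                      protocol = "rotation_x"),
          make_trials("z", runif(40) < zvh, subject = subject,
                      protocol = "zero_vs_high"),
          make_trials("h", runif(40) < hvz, subject = subject,
                      protocol = "high_vs_zero"))
  }
  set.seed(5)
  a <- do.call(rbind, lapply(1:6, function(i)
    tr(paste0("a", i), 0.8, 0.7, 0.8, 0.5)))
  # identical groups: all statistics at zero
  sc <- species_comparison(a, a)
  expect_equal(sc$normalized_test$statistic, 0)
  expect_equal(sc$interaction$statistic, 0)

  # zero-variance offset flags the degenerate limit
  one <- tr("a1", 1, 1, 1, 0)   # deterministic accuracies
  two <- tr("b1", 1, 1, 0, 1)
  sc2 <- species_comparison(rbind(one, one), rbind(two, two))
  expect_true(sc2$interaction$degenerate)
  expect_equal(sc2$interaction$statistic, Inf)
})
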