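# Synthetic observers and the session structure.

test_that("choice probability follows the lapse-probit rule", {
  o <- observer_model(rep(1, 13), decision_noise = 1, lapse = 1)
  expect_equal(choice_probability(o, rnorm(13)), 0.5)

  o2 <- observer_model(rep(1, 13), decision_noise = 1, lapse = 0)
  expect_equal(choice_probability(o2, rep(0, 13)), 0.5)

  o3 <- observer_model(rep(1, 13), decision_noise = 1e-9, lapse = 0)
  expect_equal(choice_probability(o3, rep(1, 13)), 1)
  expect_equal(choice_probability(o3, rep(-1, 13)), 0)

  # hand-computed value
  o4 <- observer_model(c(1, rep(0, 12)), decision_noise = 2, lapse = 0.2)
  expect_equal(choice_probability(o4, c(1.5, rnorm(12))),
               0.1 + 0.8 * pnorm(0.75))
})

test_that("observer construction validates its parameters", {
  expect_error(observer_model(rep(1, 12), 1), "13")
  expect_error(observer_model(rep(-1, 13), 1), "non-negative")
  expect_error(observer_model(rep(1, 13), 0), "positive")
  expect_error(observer_model(rep(1, 13), 1, lapse = 2), "lapse")
})

test_that("species presets encode the intended strategies", {
  pre <- species_presets()
  expect_equal(sum(pre$rat_like$layer_weights[11:13]), 0)
  expect_equal(sum(pre$rat_like$layer_weights[4:10]), 1)
  expect_equal(sum(pre$human_like$layer_weights[11:13]), 1)
  expect_gt(pre$rat_like$lapse, pre$human_like$lapse)
})

test_that("decision-noise normalisation scales by the drive spread", {
  o <- observer_model(c(rep(0, 12), 1), decision_noise = 2, lapse = 0)
  m <- matrix(0, 4, 13)
  m[, 13] <- c(-3, -1, 1, 3)   # population SD sqrt(5)
  o2 <- normalize_decision_noise(o, m)
  expect_equal(o2$decision_noise, 2 * sqrt(5))
})

make_score_matrix <- function(values) {
  m <- matrix(rep(values, each = 13), ncol = 13, byrow = TRUE,
              dimnames = list(paste0("p", seq_along(values)),
                              paste0("L", 1:13)))
  m
}

test_that("simulated sessions honour the session structure", {
  m <- make_score_matrix(c(0.5, -0.5, 1.5))
  o <- observer_model(rep(1, 13), 1, lapse = 0.1)
  tt <- simulate_sessions(o, m, old_scores = rep(2, 13),
                          config = session_config("testing"),
                          n_sessions = 3, seed = 5)
  first <- tt[!tt$is_correction, ]
  # exactly one third old trials among first presentations
  expect_equal(as.vector(tapply(first$is_old, first$session, sum)),
               rep(40, 3))
  expect_equal(as.vector(tapply(first$is_old, first$session, length)),
               rep(120L, 3))
  # corrections only after errors, only on old pairs in testing
  expect_true(all(tt$is_old[tt$is_correction]))
  ic <- which(tt$is_correction)
  expect_true(all(!tt$correct[ic - 1] | tt$is_correction[ic - 1]))
  # within a correction run everything but the final trial is incorrect
  runs <- rle(tt$is_correction)
  expect_true(all(tt$pair_id[tt$is_correction] == "old"))

  # determinism
  tt2 <- simulate_sessions(o, m, old_scores = rep(2, 13),
                           config = session_config("testing"),
                           n_sessions = 3, seed = 5)
  expect_identical(tt, tt2)
})

test_that("a pure-lapse observer performs at chance", {
  m <- make_score_matrix(seq(-2, 2, length.out = 8))
  o <- observer_model(rep(1, 13), 1, lapse = 1)
  tt <- simulate_sessions(o, m, config = session_config("training"),
                          n_sessions = 40, seed = 8)
  first <- tt[!tt$is_correction, ]
  n <- nrow(first)
  expect_lt(abs(mean(first$correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("a noiseless observer with positive drives is always correct", {
  m <- make_score_matrix(c(1, 2, 3))
  o <- observer_model(rep(1, 13), 1e-9, lapse = 0)
  tt <- simulate_sessions(o, m, config = session_config("training"),
                          n_sessions = 2, seed = 3)
  expect_true(all(tt$correct))
  expect_false(any(tt$is_correction))
})

test_that("random reward affects the reward flag only", {
  m <- make_score_matrix(rep(10, 4))   # always correct
  o <- observer_model(rep(1, 13), 1e-9, lapse = 0)
  tt <- simulate_sessions(o, m, old_scores = rep(10, 13),
                          config = session_config("testing"),
                          n_sessions = 20, seed = 4)
  new <- tt[!tt$is_old & !tt$is_correction, ]
  expect_true(all(new$correct))
  rate <- mean(new$rewarded)
  expect_lt(abs(rate - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(new)))
  old <- tt[tt$is_old, ]
  expect_true(all(old$rewarded == old$correct))
})

test_that("unscored pairs are rejected", {
  m <- make_score_matrix(c(1, NA))
  o <- observer_model(rep(1, 13), 1, lapse = 0)
  expect_error(simulate_sessions(o, m, config = session_config("training")),
               "unscored")
})
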