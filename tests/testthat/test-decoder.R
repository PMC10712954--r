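# Layer-wise linear readouts, classification scores, noise calibration.

test_that("a separable two-point toy problem is fit perfectly", {
  bb <- toy_backbone()
  imgs <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(-1, 0, 0, 0), 2))
  ens <- fit_decoder(imgs, c("target", "distractor"), bb,
                     n_components = 2)
  expect_equal(ens$layers$lin1$training_accuracy, 1)
  d <- predict(ens, imgs)
  expect_gt(d[1, 1], 0)
  expect_lt(d[2, 1], 0)
})

test_that("degenerate inputs are rejected", {
  bb <- toy_backbone()
  same <- list(matrix(1, 2, 2), matrix(1, 2, 2))
  expect_error(fit_decoder(same, c("target", "distractor"), bb),
               "zero variance")
  expect_error(fit_decoder(same, c("target", "target"), bb), "both classes")
})

test_that("noiseless readouts separate the training stimuli at every layer", {
  ens <- fx_ensemble()
  acc <- vapply(ens$layers, function(l) l$training_accuracy, numeric(1))
  expect_true(all(acc == 1))
  expect_true(all(acc[c("fc6", "fc7", "fc8")] == 1))
})

test_that("classification scores are antisymmetric and zero on identity", {
  ens <- fx_ensemble()
  tr <- fx_training()
  set.seed(5)
  for (i in 1:4) {
    a <- tr$images[[sample(length(tr$images), 1)]]
    b <- tr$images[[sample(length(tr$images), 1)]]
    s_ab <- classification_score(ens, a, b)
    s_ba <- classification_score(ens, b, a)
    expect_equal(s_ab, -s_ba)
  }
  s_aa <- classification_score(ens, tr$images[[1]], tr$images[[1]])
  expect_equal(unname(s_aa), rep(0, 13))
})

test_that("decisions cohere with scores and the base pair is solved late", {
  ens <- fx_ensemble()
  sc <- score_pairs(ens, protocol_pairs("training"),
                    cache = fx_render_cache())
  expect_equal(sc$decision, sc$classification_score > 0)
  expect_true(all(sc$classification_score[sc$layer %in%
                                            c("fc6", "fc7", "fc8")] > 0))
})

test_that("PCA round-trips the training activations when all components
           are retained", {
  ens <- fx_ensemble()
  tr <- fx_training()
  acts <- objstrat:::extract_features_set(ens$backbone,
                                          lapply(tr$images, function(i)
                                            i$pixels))
  for (nm in c("pool5", "fc8")) {
    l <- ens$layers[[nm]]
    A <- acts[[nm]]
    Z <- sweep(sweep(A, 2, l$center) %*% l$rotation, 2, l$sdev, "/")
    back <- sweep(Z, 2, l$sdev, "*") %*% t(l$rotation)
    back <- sweep(back, 2, l$center, "+")
    expect_lt(max(abs(back - A)), 1e-8 * max(1, max(abs(A))))
  }
})

test_that("scaling the hyperplane leaves distances and scores unchanged", {
  ens <- fx_ensemble()
  tr <- fx_training()
  d0 <- predict(ens, tr$images[1:3])
  ens2 <- ens
  for (nm in names(ens2$layers)) {
    ens2$layers[[nm]]$w <- 3.7 * ens2$layers[[nm]]$w
    ens2$layers[[nm]]$b <- 3.7 * ens2$layers[[nm]]$b
  }
  expect_equal(predict(ens2, tr$images[1:3]), d0)
})

test_that("fitting is deterministic given the seed", {
  tr <- fx_training()
  e1 <- fit_decoder(tr$images[1:8], tr$labels[1:8], noise_sd = 0.4,
                    seed = 99)
  e2 <- fit_decoder(tr$images[1:8], tr$labels[1:8], noise_sd = 0.4,
                    seed = 99)
  expect_identical(coef(e1), coef(e2))
})

test_that("calibration returns sd 0 when the target equals noiseless
           accuracy", {
  tr <- fx_training()
  nm <- calibrate_noise(synthetic_backbone(), tr$images, tr$labels,
                        target = 1, iters = 3L, seed = 1)
  expect_equal(nm$sd, 0)
  expect_equal(nm$achieved, 1)
})

test_that("training accuracy decreases along the evaluation-noise schedule", {
  tr <- fx_training()
  imgs <- tr$images[c(1:4, 13:16)]
  labs <- tr$labels[c(1:4, 13:16)]
  bb <- synthetic_backbone()
  pix <- lapply(imgs, function(i) i$pixels)
  base <- objstrat:::with_seed(77, lapply(1:6, function(i)
    lapply(pix, function(m) matrix(rnorm(length(m)), nrow(m)))))
  acc_at <- function(sd) {
    ens <- fit_decoder(imgs, labs, bb, noise_sd = sd, seed = 3)
    mean(vapply(base, function(noise) {
      noisy <- mapply(function(m, e) m + sd * e, pix, noise,
                      SIMPLIFY = FALSE)
      mean((predict(ens, noisy) > 0) == (labs == "target"))
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.5, 1.5), acc_at, numeric(1))
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0.02))
})

test_that("noiseless generalization on the training pairs is perfect with a
           zero-width interval", {
  ens <- fx_ensemble()
  lg <- layer_generalization(ens, protocol_pairs("training"),
                             cache = fx_render_cache())
  expect_equal(lg$accuracy, rep(1, 13))
  expect_equal(lg$ci_hi - lg$ci_lo, rep(0, 13))
})

test_that("overwhelming evaluation noise drives generalization to chance", {
  ens <- fx_ensemble()
  lg <- layer_generalization(ens, protocol_pairs("size"), noise_sd = 25,
                             iters = 30L, seed = 41,
                             cache = fx_render_cache())
  # binomial-oracle band: 4 pairs x 30 iterations of near-coin-flip decisions
  half_width <- 3 * sqrt(0.25 / (4 * 30))
  expect_true(all(abs(lg$accuracy - 0.5) < half_width + 0.05))
  expect_true(all(lg$ci_hi - lg$ci_lo > 0))
})
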