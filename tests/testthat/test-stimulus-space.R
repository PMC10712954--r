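# Rendering and stimulus-space combinatorics.

test_that("rendering is deterministic and the identity rotation is exact", {
  spec <- stimulus_spec(shape_params(2, 1))
  a <- render_stimulus(spec)
  b <- render_stimulus(spec)
  expect_identical(a$pixels, b$pixels)
  expect_equal(dim(a$pixels), c(100L, 100L))
  expect_true(all(is.finite(a$pixels)))
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))

  # explicit zero rotation through the general rotation path
  z <- render_stimulus(stimulus_spec(shape_params(2, 1),
                                     stim_transform(0, 0, 0)))
  expect_identical(a$pixels, z$pixels)
})

test_that("left/right lighting of a symmetric shape mirrors the image", {
  for (conc in c(0L, 5L, 10L)) {
    l <- render_stimulus(stimulus_spec(shape_params(conc, 0),
                                       stim_transform(light_location = "left")))
    r <- render_stimulus(stimulus_spec(shape_params(conc, 0),
                                       stim_transform(light_location = "right")))
    expect_identical(l$pixels, r$pixels[, rev(seq_len(100))])
  }
})

test_that("shape and transform constructors validate their domains", {
  expect_error(shape_params(11, 0), "concavity")
  expect_error(shape_params(0, 4), "alignment")
  expect_error(stim_transform(rot_x = 45), "rotation")
  expect_error(stim_transform(size_scale = 0.5), "size_scale")
  expect_error(stim_transform(light_location = "below"))
})

test_that("enumeration counts equal the product of axis cardinalities", {
  expect_equal(nrow(enumerate_space()), 75460L)
  expect_equal(nrow(enumerate_space(alignment = 0, concavity = 0,
                                    rot_x = 0, rot_y = 0, rot_z = 0,
                                    light_location = "front")), 1L)
  # 4x4 sub-grid, x rotations only
  expect_equal(nrow(enumerate_space(alignment = 0:3,
                                    concavity = default_subgrid_columns(),
                                    rot_y = 0, rot_z = 0,
                                    light_location = "front")), 112L)

  # property: random axis subsets
  set.seed(7)
  for (i in 1:10) {
    al <- sample(0:3, sample(1:4, 1))
    co <- sample(0:10, sample(1:11, 1))
    rx <- sample(ROTATION_ANGLES <- seq(0, 180, 30), sample(1:7, 1))
    li <- sample(c("front", "left", "right", "up", "under"),
                 sample(1:5, 1))
    g <- enumerate_space(al, co, rx, 0, 0, li)
    expect_equal(nrow(g),
                 length(al) * length(co) * length(rx) * length(li))
    expect_equal(nrow(unique(g)), nrow(g))
  }
})

test_that("silhouette width grows strictly with the concavity level", {
  widths <- vapply(0:10, function(l) {
    w <- objstrat:::silhouette_widths(
      render_cached_test(stimulus_spec(shape_params(l, 0))))
    mean(w[w > 0])
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the trained distractor is brighter than the trained target", {
  bp <- base_pair()
  expect_gt(brightness(render_cached_test(bp$distractor)),
            brightness(render_cached_test(bp$target)))
})

test_that("sub-grid selection matches the brute-force objective", {
  # oracle space: dissimilarity exactly linear in the concavity index
  lin <- abs(outer(0:10, 0:10, "-")) * 2.5
  sel <- select_subgrid(lin)
  # brute force over all 330 subsets with the documented lexicographic
  # objective, written independently of the implementation
  lex_lt <- function(a, b) {
    d <- a - b
    i <- which(abs(d) > 1e-12)[1]
    !is.na(i) && d[i] < 0
  }
  best <- NULL
  for (cols in utils::combn(0:10, 4, simplify = FALSE)) {
    span <- lin[cols[1] + 1, cols[4] + 1]
    gaps <- c(lin[cols[1] + 1, cols[2] + 1], lin[cols[2] + 1, cols[3] + 1],
              lin[cols[3] + 1, cols[4] + 1])
    key <- c(-span, stats::var(gaps), abs(gaps[1] - gaps[3]), cols)
    if (is.null(best) || lex_lt(key, best)) best <- key
  }
  expect_equal(sel$columns, best[4:7])
  expect_equal(sel$columns, c(0, 3, 7, 10))  # symmetric tie-break

  # k equal to the grid width returns the grid unchanged
  expect_equal(select_subgrid(lin, k = 11)$columns, 0:10)
  expect_error(select_subgrid(lin, k = 12), "fewer")
})

test_that("diagonal role labelling partitions the 4x4 grid as 4/6/6", {
  roles <- outer(0:3, 0:3, subgrid_roles)
  expect_equal(sum(roles == "ambiguous"), 4L)
  expect_equal(sum(roles == "target"), 6L)
  expect_equal(sum(roles == "distractor"), 6L)
  # trained corners are unambiguous
  expect_equal(roles[1, 1], "target")
  expect_equal(roles[4, 4], "distractor")
})

test_that("protocol pair counts match the design", {
  counts <- c(training = 1L, dimension_learning = 3L, transformations = 25L,
              rotation_x = 36L, rotation_y = 36L, rotation_z = 36L,
              light_location = 16L, size = 4L, position = 25L,
              combination_rotation = 36L)
  for (nm in names(counts))
    expect_equal(nrow(protocol_pairs(nm)$pairs), unname(counts[nm]),
                 label = nm)
  expect_error(protocol_pairs("zero_vs_high"), "selection")
  expect_error(protocol_pairs("no_such"), "arg")
  # roles are consistent in every fixed protocol's pair list
  p <- protocol_pairs("rotation_y")$pairs
  expect_true(all(p$target_role == "target"))
  expect_true(all(p$distractor_role == "distractor"))
})

test_that("the training set holds the three training protocols' stimuli", {
  tr <- training_stimuli()
  expect_equal(nrow(unique(tr)), nrow(tr))
  expect_setequal(unique(tr$role), c("target", "distractor"))
  expect_equal(sum(tr$role == "target"), sum(tr$role == "distractor"))
})

test_that("brightness and pixel dissimilarity behave as image functionals", {
  z <- matrix(0, 100, 100); o <- matrix(1, 100, 100)
  expect_equal(brightness(z), 0)
  expect_equal(brightness(o), 1)
  chk <- matrix(rep(c(0, 1), 5000), 100, 100)
  expect_equal(brightness(chk), 0.5)

  expect_equal(pixel_dissimilarity(z, z), 0)
  expect_equal(pixel_dissimilarity(z, o), 100)
  set.seed(11)
  a <- matrix(runif(400), 20, 20); b <- matrix(runif(400), 20, 20)
  expect_equal(pixel_dissimilarity(a, b), sqrt(sum((a - b)^2)))
  expect_error(pixel_dissimilarity(a, matrix(0, 10, 10)), "dimensions")
})

test_that("pixel dissimilarity is a metric on random image triples", {
  set.seed(23)
  for (i in 1:20) {
    a <- matrix(runif(100), 10, 10); b <- matrix(runif(100), 10, 10)
    c_ <- matrix(runif(100), 10, 10)
    dab <- pixel_dissimilarity(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, pixel_dissimilarity(b, a))
    expect_lte(pixel_dissimilarity(a, c_),
               dab + pixel_dissimilarity(b, c_) + 1e-12)
  }
  expect_equal(pixel_dissimilarity(matrix(0.3, 5, 5), matrix(0.3, 5, 5)), 0)
})

test_that("the candidate pool crosses shapes with all transformations", {
  pool <- candidate_pool()
  expect_equal(nrow(pool$targets), 5145L)
  expect_equal(nrow(pool$distractors), 5145L)
  expect_equal(pool$n_pairs, 26471025)
  expect_true(all(pool$targets$role == "target"))
  expect_error(candidate_pool(target_cells = rbind(c(3, 3))), "not a target")
})
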