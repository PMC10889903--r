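test_that("pair distances match the brute-force oracle", {
  set.seed(31)
  for (i in 1:5) {
    d <- c(sample(2:5, 2, replace = TRUE), sample(1:4, 1))
    a <- array(rnorm(prod(d)), dim = d)
    b <- array(rnorm(prod(d)), dim = d)
    expect_equal(pair_distance(a, b), oracle_distance(a, b, "euclidean"),
      tolerance = 1e-12
    )
    expect_equal(
      pair_distance(a, b, "sq_sum"), oracle_distance(a, b, "sq_sum"),
      tolerance = 1e-12
    )
    expect_equal(pair_distance(a, b, "sq_sum"), pair_distance(a, b)^2)
    expect_identical(pair_distance(a, a), 0)
  }
  expect_error(
    pair_distance(array(1, c(2, 2, 1)), array(1, c(2, 3, 1))),
    "identical shape"
  )
})

test_that("level exemplars are the stimuli nearest each bin centre", {
  grid <- enumerate_stimulus_grid()
  strengths <- aggregate_strengths(
    simulate_responses(grid, response_model_params())
  )
  ex <- select_level_exemplars(strengths)
  expect_equal(nrow(ex), 8)
  expect_equal(ex$level, 1:8)
  expect_equal(ex$bin_center_deg, (1:8 - 0.5) * 0.1)
  ord <- strengths[order(strengths$stimulus_id), ]
  for (k in 1:8) {
    best <- min(abs(ord$strength_deg - (k - 0.5) * 0.1))
    expect_equal(abs(ex$strength_deg[k] - (k - 0.5) * 0.1), best)
  }
  expect_error(
    select_level_exemplars(strengths[, "stimulus_id"]),
    "lack columns"
  )
})

test_that("cross-set RDMs are mean-normalized with correct orientation", {
  grid <- small_grid()
  ds <- render_small(build_training_pool(per_level = 2L, grid = grid, seed = 8L))
  m <- train(make_model(), ds, hp = hyperparams(epochs = 1L))
  perceived <- lapply(c(0.1, 0.3, 0.6), function(t) {
    render_tilted(grid[1, ], rep(t, 4))
  })
  real <- lapply(1:3, function(i) render_illusion(grid[i, ]))
  for (layer in c("conv1", "conv4")) {
    rdm <- build_cross_rdm(perceived, real, m,
      layer = layer, downscale = 4L
    )
    expect_s3_class(rdm, "cross_rdm")
    expect_equal(dim(rdm$R), c(3, 3))
    expect_lt(abs(mean(rdm$R) - 1), 1e-9)
    expect_equal(rdm$R, rdm$r / mean(rdm$r))
    expect_equal(rdm$layer_id, layer)
    # spot-check one raw entry against a direct feature distance
    f_p <- extract_features(m, perceived[[2]], layer, downscale = 4L)
    f_r <- extract_features(m, real[[3]], layer, downscale = 4L)
    expect_equal(rdm$r[2, 3], pair_distance(f_p, f_r), tolerance = 1e-12)
  }
  expect_error(build_cross_rdm(perceived, real[1:2], m), "equal length")
})

test_that("identical image sets give a zero-diagonal RDM", {
  grid <- small_grid()
  m <- make_model()
  imgs <- lapply(1:3, function(i) render_illusion(grid[i, ]))
  rdm <- build_cross_rdm(imgs, imgs, m, downscale = 4L)
  expect_equal(diag(rdm$r), rep(0, 3))
  expect_lt(abs(mean(rdm$R) - 1), 1e-9)
})

test_that("the RDM stack covers the requested layers and exemplars", {
  grid <- enumerate_stimulus_grid()
  strengths <- aggregate_strengths(
    simulate_responses(grid, response_model_params())
  )
  m <- make_model()
  stack <- cross_rdm_stack(m, strengths, grid,
    layers = c("conv1", "conv3"), downscale = 4L
  )
  expect_named(stack, c("conv1", "conv3"))
  expect_equal(dim(stack$conv1$R), c(8, 8))
  expect_lt(abs(mean(stack$conv3$R) - 1), 1e-9)
  expect_equal(nrow(attr(stack, "exemplars")), 8)
})

test_that("the depth profile stratifies by class and correctness", {
  grid <- small_grid()
  ds <- render_small(build_training_pool(per_level = 3L, grid = grid, seed = 10L))
  m <- train(make_model(), ds, hp = hyperparams(epochs = 1L))
  strengths <- aggregate_strengths(
    simulate_responses(grid, response_model_params())
  )
  prof <- depth_profile(m, strengths, grid,
    layers = c("conv2", "conv4"), downscale = 4L
  )
  expect_setequal(unique(prof$layer_id), c("conv2", "conv4"))
  # every stimulus appears exactly once per layer
  per_layer <- tapply(prof$n, prof$layer_id, sum)
  expect_true(all(per_layer == nrow(grid)))
  expect_true(all(prof$mean_distance >= 0))
  expect_error(
    depth_profile(m, strengths[1:2, ], grid),
    "cover every grid stimulus"
  )
})

test_that("the framework score reduces maps and RDMs as documented", {
  h1 <- structure(matrix(c(0, 1, 0.5, 0.25), 2, 2),
    class = c("heatmap", "matrix")
  )
  h2 <- structure(matrix(c(1, 0, 0.5, 0.75), 2, 2),
    class = c("heatmap", "matrix")
  )
  R <- matrix(c(0.5, 1.2, 1.3, 0.6, 0.4, 1.5, 1.4, 1.1, 1.0), 3, 3)
  rdm <- structure(
    list(r = R, R = R / mean(R), layer_id = "conv1", mode = "euclidean",
      levels = 1:3),
    class = "cross_rdm"
  )
  fs <- framework_score(list(C1 = h1, C2 = h2), rdm)
  Rn <- R / mean(R)
  expect_equal(
    fs$rdm_summary,
    mean(Rn[row(Rn) != col(Rn)]) - mean(diag(Rn))
  )
  expect_equal(fs$gradcam_summary, mean(abs(unclass(h1) - unclass(h2))))
  expect_equal(fs$score, 0.5 * fs$rdm_summary + 0.5 * fs$gradcam_summary)
  expect_equal(fs$layer_id, "conv1")
  expect_error(
    framework_score(list(C1 = h1, C2 = h2), rdm, synthesis = "mean"),
    "unknown synthesis"
  )
  expect_error(
    framework_score(list(C1 = h1), rdm),
    "C1 and C2"
  )
  expect_error(
    framework_score(list(C1 = h1, C2 = h2), rdm, weights = c(a = 1, b = 1)),
    "named"
  )
})
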