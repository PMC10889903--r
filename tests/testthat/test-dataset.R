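test_that("the training pool is level- and class-balanced", {
  pool <- build_training_pool(per_level = 50L, seed = 4L)
  expect_equal(nrow(pool), 400)
  expect_equal(as.vector(table(pool$level)), rep(50, 8))
  expect_equal(as.vector(table(pool$class_label)), c(200, 200))
  expect_false(anyDuplicated(pool$image_id) > 0)
})

test_that("pool tilts lie in the level bin with the setting's sign", {
  pool <- build_training_pool(per_level = 40L, seed = 9L)
  mag <- abs(pool$tilt1)
  expect_true(all(mag > (pool$level - 1) * 0.1))
  expect_true(all(mag <= pool$level * 0.1))
  expect_true(all(pool$tilt1[pool$setting == "I"] > 0))
  expect_true(all(pool$tilt1[pool$setting == "II"] < 0))
  # all four bars share the same tilt
  expect_equal(pool$tilt1, pool$tilt2)
  expect_equal(pool$tilt1, pool$tilt4)
})

test_that("stimulus parameters are sampled independently of the label", {
  pool <- build_training_pool(per_level = 250L, seed = 11L)
  # setting and width frequencies must not differ systematically by class
  p_I <- tapply(pool$setting == "I", pool$class_label, mean)
  expect_true(all(abs(p_I - 0.5) < 0.08))
  wtab <- table(pool$class_label, pool$diamond_width_px)
  expect_true(all(abs(wtab / rowSums(wtab) - 1 / 6) < 0.05))
})

test_that("pool generation is reproducible and validates per_level", {
  expect_identical(
    build_training_pool(per_level = 10L, seed = 2L),
    build_training_pool(per_level = 10L, seed = 2L)
  )
  expect_error(build_training_pool(per_level = 0L), "positive")
})

test_that("the train/val split is a stratified 3:1 partition", {
  pool <- build_training_pool(per_level = 40L, seed = 1L)
  sp <- split_train_val(pool, ratio = c(3, 1), seed = 1L)
  expect_equal(nrow(sp$train) + nrow(sp$val), nrow(pool))
  expect_length(intersect(sp$train$image_id, sp$val$image_id), 0)
  expect_setequal(c(sp$train$image_id, sp$val$image_id), pool$image_id)
  expect_equal(as.vector(table(sp$train$level)), rep(30, 8))
  expect_equal(as.vector(table(sp$val$level)), rep(10, 8))
  expect_equal(unique(sp$train$split), "train")
  expect_equal(unique(sp$val$split), "val")
  expect_error(split_train_val(pool[0, ]), "empty")
})

test_that("the independent test manifest has the stated size and balance", {
  man <- build_independent_test(n = 240L, seed = 7L)
  expect_equal(nrow(man), 240)
  expect_equal(as.vector(table(man$level)), rep(30, 8))
  expect_equal(unique(man$split), "test_tilted")
  expect_error(build_independent_test(n = 7L), "even")
})

test_that("independent and training pools are draw-disjoint by seed", {
  pool <- build_training_pool(per_level = 20L, seed = 1L)
  test <- build_independent_test(n = 160L, seed = 2L)
  # different seed streams: the tilt draws must not coincide
  expect_false(any(round(pool$tilt1, 12) %in% round(test$tilt1, 12)))
})

test_that("the illusion test manifest carries human-derived labels", {
  grid <- enumerate_stimulus_grid()
  strengths <- aggregate_strengths(
    simulate_responses(grid, response_model_params())
  )
  man <- build_illusion_test(strengths, grid)
  expect_equal(nrow(man), 144)
  expect_equal(unique(man$split), "test_illusion")
  expect_true(all(is.na(man$tilt1)))
  idx <- match(man$stimulus_id, strengths$stimulus_id)
  expect_equal(man$class_label, strengths$illusion_class[idx])
  expect_error(build_illusion_test(strengths[1:10, ], grid), "missing stimuli")
})

test_that("rendering a manifest yields a normalized in-memory dataset", {
  grid <- small_grid()
  pool <- build_training_pool(per_level = 1L, grid = grid, seed = 5L)
  ds <- render_manifest(pool, downscale = 4L)
  expect_s3_class(ds, "grating_dataset")
  expect_equal(dim(ds$x), c(8, 40 * 140 * 3))
  expect_equal(ds$height, 40)
  expect_equal(ds$width, 140)
  expect_true(all(ds$x >= 0 & ds$x <= 1))
  expect_equal(ds$y, as.integer(pool$class_label == "C2"))
  expect_identical(ds$x, render_manifest(pool, downscale = 4L)$x)
  expect_error(render_manifest(pool[0, ]), "empty")
})

test_that("rendering a manifest to disk writes one PNG per row", {
  grid <- small_grid()
  pool <- build_training_pool(per_level = 1L, grid = grid, seed = 5L)[1:2, ]
  dir <- withr::local_tempdir()
  render_manifest(pool, dir = dir)
  files <- list.files(dir, pattern = "\\.png$", recursive = TRUE)
  expect_length(files, 2)
})
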