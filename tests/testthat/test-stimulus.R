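test_that("grid enumeration is deterministic, unique and correctly ordered", {
  grid <- enumerate_stimulus_grid()
  expect_equal(nrow(grid), 144)
  expect_false(anyDuplicated(grid$stimulus_id) > 0)
  # colour-major, then width, then setting
  expect_equal(grid$stimulus_id[1:4], c("red_w5_I", "red_w5_II", "red_w6_I", "red_w6_II"))
  expect_equal(grid$color_name[1:12], rep("red", 12))
  expect_s3_class(attr(grid, "canvas"), "canvas_spec")
})

test_that("grid enumeration rejects empty factors and bad settings", {
  pal <- default_color_ring()
  expect_error(enumerate_stimulus_grid(pal[0, ]), "non-empty")
  expect_error(enumerate_stimulus_grid(widths = integer()), "non-empty")
  expect_error(enumerate_stimulus_grid(settings = "III"), "settings")
})

test_that("canvas spec validates its geometry", {
  expect_error(canvas_spec(bar_length_px = 600), "width_px")
  expect_error(canvas_spec(stripe_width_px = 0))
  cv <- canvas_spec()
  expect_equal(cv$width_px, 560L)
  expect_equal(cv$height_px, 160L)
  expect_equal(cv$bar_count, 4L)
  expect_equal(cv$diamond_pitch_px, 20L)
  expect_equal(cv$background_blue, c(0, 0, 96))
})

test_that("rendering is deterministic and 8-bit valued", {
  stim <- small_grid()[1, ]
  a <- render_illusion(stim)
  b <- render_illusion(stim)
  expect_identical(a, b)
  expect_equal(dim(a), c(160, 560, 3))
  v <- as.vector(unclass(a))
  expect_true(all(v >= 0 & v <= 255))
  expect_true(all(v == round(v)))
})

test_that("zero tilt reproduces the illusion render exactly", {
  stim <- small_grid()[2, ]
  expect_equal(
    unclass(render_tilted(stim, rep(0, 4))),
    unclass(render_illusion(stim))
  )
})

test_that("horizontal mirroring swaps settings and negates tilt", {
  grid <- small_grid()
  s1 <- grid[grid$color_name == "red" & grid$diamond_width_px == 5 &
    grid$setting == "I", ]
  s2 <- grid[grid$color_name == "red" & grid$diamond_width_px == 5 &
    grid$setting == "II", ]
  tilt <- c(0.3, -0.2, 0.5, 0.1)
  a <- unclass(render_tilted(s1, tilt))
  b <- unclass(render_tilted(s2, -tilt))
  expect_equal(a, b[, dim(b)[2]:1, , drop = FALSE], ignore_attr = TRUE)
  # and for the horizontal case too
  ia <- unclass(render_illusion(s1))
  ib <- unclass(render_illusion(s2))
  expect_equal(ia, ib[, dim(ib)[2]:1, , drop = FALSE], ignore_attr = TRUE)
})

test_that("tilt rendering validates its angles", {
  stim <- small_grid()[1, ]
  expect_error(render_tilted(stim, c(0, 0)), "one angle per bar")
  expect_error(render_tilted(stim, c(0, 0, NA, 0)), "finite")
  expect_error(render_tilted(stim, c(0, 0, 0, 6)), "max_tilt")
})

test_that("oversized diamonds are rejected", {
  stim <- small_grid()[1, ]
  stim$diamond_width_px <- 25L
  expect_error(render_illusion(stim), "diamond width")
})

test_that("a moment-based oracle recovers the rendered tilt", {
  stim <- small_grid()[1, ]
  canvas <- canvas_spec()
  tilt <- c(2, -2, 1.5, 0)
  img <- render_tilted(stim, tilt, canvas, scene = "plain")
  for (k in 1:4) {
    est <- oracle_bar_angle(img, canvas, k)
    expect_lt(abs(est - tilt[k]), 0.2, label = paste("bar", k))
  }
})

test_that("downscaling matches a block-mean oracle", {
  set.seed(5)
  img <- array(runif(12 * 8 * 3) * 255, dim = c(12, 8, 3))
  out <- downscale_image(img, 4L)
  expect_equal(dim(out), c(3, 2, 3))
  for (ch in 1:3) {
    for (i in 1:3) {
      for (j in 1:2) {
        blk <- img[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), ch]
        expect_equal(out[i, j, ch], mean(blk))
      }
    }
  }
  expect_equal(downscale_image(img, 1L), img)
  expect_error(downscale_image(img, 5L), "divisible")
})

test_that("PNG round-trip preserves pixels and writes a sidecar", {
  stim <- small_grid()[1, ]
  img <- render_illusion(stim)
  path <- withr::local_tempfile(fileext = ".png")
  write_grating_png(img, path)
  back <- png::readPNG(path) * 255
  expect_equal(unclass(img), back, ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$color_name, stim$color_name)
  expect_equal(meta$diamond_width_px, stim$diamond_width_px)
  expect_equal(meta$setting, stim$setting)
})
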