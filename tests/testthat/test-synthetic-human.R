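test_that("illusion strength is the mean absolute adjusted angle", {
  expect_equal(illusion_strength(c(0.3, -0.5, 0.4, -0.2)), 0.35)
  expect_equal(illusion_strength(c(0, 0, 0, 0)), 0)
  m <- rbind(c(0.1, 0.1, 0.1, 0.1), c(-0.2, 0.2, -0.2, 0.2))
  expect_equal(illusion_strength(m), c(0.1, 0.2))
  expect_equal(
    illusion_strength(as.data.frame(m)),
    c(0.1, 0.2)
  )
  expect_error(illusion_strength(c(0.1, 0.2)), "four angles")
  expect_error(illusion_strength(c(0.1, NA, 0.2, 0.3)), "finite")
})

test_that("level binning is left-open right-closed with clamping", {
  expect_equal(assign_level(c(0, 0.35, 0.4, 0.95)), c(1L, 4L, 4L, 8L))
  expect_equal(assign_level(0.4 + 1e-12), 4L) # numerically-at-the-edge
  expect_equal(assign_level(0.41), 5L)
  expect_error(assign_level(-0.1), "non-negative")
  expect_error(assign_level(NaN), "finite")
})

test_that("class assignment splits levels 1-4 vs 5-8", {
  cls <- assign_class(1:8)
  expect_equal(as.character(cls), c(rep("C1", 4), rep("C2", 4)))
  expect_equal(levels(cls), c("C1", "C2"))
  expect_error(assign_class(0), "1..8")
  expect_error(assign_class(9), "1..8")
})

test_that("the base table encodes the hue/width structure", {
  tab <- default_base_table()
  expect_equal(nrow(tab), 72)
  expect_true(all(tab$base_strength_deg >= 0 & tab$base_strength_deg <= 0.8))
  weak <- c("green", "spring green", "cyan", "yellow-green", "yellow")
  w_tab <- tab[tab$color_name %in% weak, ]
  s_tab <- tab[!tab$color_name %in% weak, ]
  expect_true(all(w_tab$base_strength_deg < 0.4))
  expect_true(all(
    s_tab$base_strength_deg[s_tab$diamond_width_px <= 8] > 0.4
  ))
  expect_true(all(
    s_tab$base_strength_deg[s_tab$diamond_width_px >= 9] < 0.4
  ))
  # strength falls off with diamond width within every hue
  by_hue <- split(tab, tab$color_name)
  for (h in by_hue) {
    ord <- h[order(h$diamond_width_px), ]
    expect_true(all(diff(ord$base_strength_deg) <= 0))
  }
})

test_that("simulated responses have the configured shape and signs", {
  grid <- enumerate_stimulus_grid()
  params <- response_model_params(n_participants = 5L, seed = 3L)
  rec <- simulate_responses(grid, params)
  expect_equal(nrow(rec), 144 * 5)
  expect_identical(rec, simulate_responses(grid, params)) # deterministic
  agg <- aggregate_strengths(rec)
  expect_true(all(agg$mean_angle1[agg$setting == "I"] > 0))
  expect_true(all(agg$mean_angle1[agg$setting == "II"] < 0))
})

test_that("simulation rejects conditions missing from the base table", {
  grid <- enumerate_stimulus_grid(widths = c(5L, 20L))
  expect_error(
    simulate_responses(grid, response_model_params()),
    "missing conditions"
  )
})

test_that("noiseless parameter recovery is exact", {
  grid <- enumerate_stimulus_grid()
  params <- response_model_params(participant_sd_deg = 0, n_participants = 4L)
  agg <- aggregate_strengths(simulate_responses(grid, params))
  base <- default_base_table()
  key <- paste(agg$color_name, agg$diamond_width_px)
  bkey <- paste(base$color_name, base$diamond_width_px)
  expect_equal(agg$strength_deg, base$base_strength_deg[match(key, bkey)])
  sign <- ifelse(agg$setting == "I", 1, -1)
  expect_equal(agg$mean_angle3, sign * agg$strength_deg)
})

test_that("aggregation derives level and class from the mean strength", {
  grid <- enumerate_stimulus_grid()
  agg <- aggregate_strengths(simulate_responses(grid, response_model_params()))
  expect_equal(nrow(agg), 144)
  expect_equal(agg$n_participants, rep(23L, 144))
  expect_equal(agg$level, assign_level(agg$strength_deg))
  expect_equal(agg$illusion_class, assign_class(agg$level))
  expect_error(aggregate_strengths(agg[0, ]), "no perceptual records")
})

test_that("angle CSVs round-trip and validate their columns", {
  grid <- small_grid()
  rec <- simulate_responses(grid, response_model_params(n_participants = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_csv(rec, path)
  back <- read_angle_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-12)
  bad <- rec[, setdiff(names(rec), "angle2")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_angle_csv(path2), "angle2")
})
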