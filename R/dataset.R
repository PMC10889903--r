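#' Build the tilted-image training pool
#'
#' Generates a manifest of tilted-bar training images balanced over the eight
#' illusion-strength levels. For each level `k`, `per_level` rows are drawn:
#' stimulus parameters (hue, diamond width, positional setting) are sampled
#' uniformly and independently of the label, the shared per-bar tilt
#' magnitude is sampled uniformly inside level `k`'s bin
#' `((k-1) * 0.1, k * 0.1]` degrees, and the tilt sign follows the positional
#' setting (I clockwise, II counterclockwise). The class label follows the
#' level (1-4 C1, 5-8 C2), so the pool is exactly class-balanced and tilt is
#' the only label-correlated image content.
#'
#' @param per_level Number of images per level (3000 reproduces the full
#'   24,000-image pool; desk-scale runs use far fewer).
#' @param grid Stimulus grid the parameters are drawn from.
#' @param seed Integer seed; manifests are reproducible bit-for-bit.
#' @param scene Passed through to rendering: `"full"` or `"plain"`.
#' @param path_prefix Directory-style prefix used when composing the unique
#'   relative `image_path` of each row.
#' @return A manifest tibble with one row per image: `image_id`,
#'   `image_path`, `split` (`NA` until [split_train_val()]), `class_label`,
#'   `level`, stimulus parameter columns and `tilt1`-`tilt4` (degrees).
#' @export
build_training_pool <- function(per_level = 3000L,
                                grid = enumerate_stimulus_grid(),
                                seed = 1L,
                                scene = c("full", "plain"),
                                path_prefix = "train_pool") {
  scene <- match.arg(scene)
  if (per_level < 1) stop("`per_level` must be a positive integer", call. = FALSE)
  n <- 8L * as.integer(per_level)
  combos <- dplyr::distinct(
    grid, .data$color_name, .data$ring_index, .data$r, .data$g, .data$b
  )
  widths <- sort(unique(grid$diamond_width_px))
  settings <- sort(unique(grid$setting))

  man <- with_seed(seed, {
    level <- rep(1:8, each = per_level)
    ci <- sample.int(nrow(combos), n, replace = TRUE)
    wd <- sample(widths, n, replace = TRUE)
    st <- sample(settings, n, replace = TRUE)
    # uniform on ((k-1)*0.1, k*0.1]
    mag <- level * 0.1 - stats::runif(n) * 0.1
    tibble::tibble(
      image_id = sprintf("%s_%06d", path_prefix, seq_len(n)),
      image_path = sprintf("%s/img_%06d.png", path_prefix, seq_len(n)),
      split = NA_character_,
      level = as.integer(level),
      class_label = assign_class(level),
      color_name = combos$color_name[ci],
      ring_index = combos$ring_index[ci],
      r = combos$r[ci], g = combos$g[ci], b = combos$b[ci],
      diamond_width_px = wd,
      setting = st,
      scene = scene,
      tilt1 = ifelse(st == "I", 1, -1) * mag,
      tilt2 = ifelse(st == "I", 1, -1) * mag,
      tilt3 = ifelse(st == "I", 1, -1) * mag,
      tilt4 = ifelse(st == "I", 1, -1) * mag
    )
  })
  attr(man, "canvas") <- attr(grid, "canvas") %||% canvas_spec()
  man
}

#' Split a manifest into training and validation sets
#'
#' Stratified by level (and therefore by class): within each level the rows
#' are split in an `a:b` ratio after seeded shuffling, so each stratum's
#' training share is within one row of the exact proportion. The two parts
#' are disjoint and their union is the input.
#'
#' @param manifest Manifest tibble from [build_training_pool()].
#' @param ratio Either a single number `a` (meaning `a:1`) or a length-2
#'   vector `c(a, b)`.
#' @param seed Integer seed for the within-stratum shuffle.
#' @return A list with elements `train` and `val`, manifests with the
#'   `split` column filled in.
#' @export
split_train_val <- function(manifest, ratio = c(3, 1), seed = 1L) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (length(ratio) == 1) ratio <- c(ratio, 1)
  if (any(ratio < 1)) stop("ratio parts must be >= 1", call. = FALSE)
  frac <- ratio[1] / sum(ratio)
  take <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$level), function(ix) {
      n_tr <- round(length(ix) * frac)
      sample(ix, n_tr)
    }), use.names = FALSE)
  })
  is_train <- seq_len(nrow(manifest)) %in% take
  train <- manifest[is_train, ]
  val <- manifest[!is_train, ]
  train$split <- "train"
  val$split <- "val"
  attr(train, "canvas") <- attr(manifest, "canvas")
  attr(val, "canvas") <- attr(manifest, "canvas")
  list(train = train, val = val)
}

#' Build the independent tilted test set
#'
#' Same generative procedure as [build_training_pool()], drawn from its own
#' seed stream, with `n` images balanced across the eight levels (any
#' remainder after dividing by eight goes to the lowest levels).
#'
#' @param n Even number of test images (1200 reproduces the full independent
#'   test set, 150 per level).
#' @inheritParams build_training_pool
#' @return A manifest tibble with `split = "test_tilted"`.
#' @export
build_independent_test <- function(n = 1200L,
                                   grid = enumerate_stimulus_grid(),
                                   seed = 2L,
                                   scene = c("full", "plain")) {
  scene <- match.arg(scene)
  if (n < 2 || n %% 2 != 0) stop("`n` must be an even number >= 2", call. = FALSE)
  base <- n %/% 8L
  extra <- n %% 8L
  counts <- base + as.integer(seq_len(8) <= extra)
  # reuse the pool generator at the largest per-level count, then trim
  man <- build_training_pool(
    per_level = max(counts), grid = grid, seed = seed, scene = scene,
    path_prefix = "independent_test"
  )
  keep <- unlist(lapply(1:8, function(k) {
    which(man$level == k)[seq_len(counts[k])]
  }), use.names = FALSE)
  man <- man[sort(keep), ]
  man$split <- "test_tilted"
  man$image_id <- sprintf("independent_test_%06d", seq_len(nrow(man)))
  man$image_path <- sprintf("independent_test/img_%06d.png", seq_len(nrow(man)))
  attr(man, "canvas") <- attr(grid, "canvas") %||% canvas_spec()
  man
}

#' Build the illusion test set (horizontal bars, human-derived labels)
#'
#' One row per grid stimulus, rendered with all bars physically horizontal
#' and labelled with the C1/C2 class derived from (synthetic or real)
#' adjustment data. A classifier trained on actually tilted images that
#' assigns C2 to these images is, like a human observer, "seeing" a tilt
#' that is not there.
#'
#' @param strengths Per-stimulus strength tibble from
#'   [aggregate_strengths()]; must cover every grid stimulus.
#' @param grid Stimulus grid.
#' @return A manifest tibble with `split = "test_illusion"` and `NA` tilts.
#' @export
build_illusion_test <- function(strengths, grid = enumerate_stimulus_grid()) {
  idx <- match(grid$stimulus_id, strengths$stimulus_id)
  if (any(is.na(idx))) {
    stop(
      "strengths are missing stimuli: ",
      paste(utils::head(grid$stimulus_id[is.na(idx)], 5), collapse = ", "),
      call. = FALSE
    )
  }
  man <- tibble::tibble(
    image_id = grid$stimulus_id,
    image_path = sprintf("illusion_test/%s.png", grid$stimulus_id),
    split = "test_illusion",
    level = strengths$level[idx],
    class_label = strengths$illusion_class[idx],
    color_name = grid$color_name,
    ring_index = grid$ring_index,
    r = grid$r, g = grid$g, b = grid$b,
    diamond_width_px = grid$diamond_width_px,
    setting = grid$setting,
    scene = "full",
    tilt1 = NA_real_, tilt2 = NA_real_, tilt3 = NA_real_, tilt4 = NA_real_,
    stimulus_id = grid$stimulus_id,
    strength_deg = strengths$strength_deg[idx]
  )
  attr(man, "canvas") <- attr(grid, "canvas") %||% canvas_spec()
  man
}

#' Render a manifest into an in-memory dataset (or PNG files)
#'
#' Renders every manifest row ([render_tilted()] for rows with tilt angles,
#' [render_illusion()] for rows without) and either collects the images into
#' an in-memory dataset ready for training, or writes them as PNGs.
#'
#' @param manifest A manifest tibble.
#' @param canvas A [canvas_spec()]; defaults to the manifest's.
#' @param downscale Integer block-averaging factor applied after rendering
#'   (2 halves each canvas dimension).
#' @param dir If non-`NULL`, images are written below `dir` following
#'   `image_path` and no pixel data is kept in memory.
#' @return Invisibly `dir` when writing files; otherwise a `grating_dataset`:
#'   a list with the image matrix `x` (rows are flattened normalized images),
#'   integer labels `y` (0 = C1, 1 = C2), `height`, `width` and the manifest.
#' @export
render_manifest <- function(manifest, canvas = NULL, downscale = 1L,
                            dir = NULL) {
  canvas <- canvas %||% attr(manifest, "canvas") %||% canvas_spec()
  n <- nrow(manifest)
  if (n == 0) stop("manifest is empty", call. = FALSE)
  h <- canvas$height_px %/% downscale
  w <- canvas$width_px %/% downscale
  x <- if (is.null(dir)) matrix(0, n, h * w * 3L) else NULL
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    img <- render_manifest_row(row, canvas)
    if (!is.null(dir)) {
      out <- file.path(dir, row$image_path)
      dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
      write_grating_png(img, out)
    } else {
      if (downscale > 1L) img <- downscale_image(img, downscale)
      x[i, ] <- image_to_input(img)
    }
  }
  if (!is.null(dir)) return(invisible(dir))
  structure(
    list(
      x = x,
      y = as.integer(manifest$class_label == "C2"),
      height = h, width = w,
      manifest = manifest
    ),
    class = "grating_dataset"
  )
}

render_manifest_row <- function(row, canvas) {
  scene <- if (!is.null(row$scene)) row$scene else "full"
  tilt <- c(row$tilt1, row$tilt2, row$tilt3, row$tilt4)
  if (any(is.na(tilt))) {
    render_illusion(row, canvas, scene = scene)
  } else {
    render_tilted(row, tilt, canvas, scene = scene)
  }
}

#' @export
print.grating_dataset <- function(x, ...) {
  cat(
    "<grating_dataset> ", nrow(x$x), " images, ",
    x$height, "x", x$width, " px, classes C1/C2 = ",
    sum(x$y == 0), "/", sum(x$y == 1), "\n",
    sep = ""
  )
  invisible(x)
}
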