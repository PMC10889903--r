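#' Canvas and scene geometry for oblique-grating stimuli
#'
#' The stimulus scene is four long horizontal coloured bars on a background of
#' interleaved black and blue vertical stripes; small black and white diamonds
#' straddle both edges of each bar in an alternating sequence. Bars are 560 px
#' long on a 560 x 160 px canvas. Quantities the original display did not pin
#' down (bar thickness, stripe width, diamond pitch, the blue tone) are
#' exposed here as configurable defaults.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param bar_length_px Length of each horizontal bar (must not exceed the
#'   canvas width).
#' @param bar_count Number of bars, evenly spaced vertically.
#' @param bar_thickness_px Bar thickness in pixels.
#' @param stripe_width_px Width of the background stripes. Stripes are indexed
#'   outward from the vertical midline so the background is mirror-symmetric.
#' @param background_black,background_blue 8-bit RGB triples for the two
#'   stripe colours.
#' @param diamond_pitch_px Spacing between consecutive diamond centres along a
#'   bar; defaults to twice the stripe width.
#' @param max_tilt_deg Largest admissible per-bar tilt magnitude, degrees.
#' @return A list of class `canvas_spec`.
#' @export
canvas_spec <- function(width_px = 560L, height_px = 160L,
                        bar_length_px = 560L, bar_count = 4L,
                        bar_thickness_px = 14L, stripe_width_px = 10L,
                        background_black = c(0, 0, 0),
                        background_blue = c(0, 0, 96),
                        diamond_pitch_px = 2L * stripe_width_px,
                        max_tilt_deg = 5) {
  stopifnot(
    width_px > 0, height_px > 0, bar_count >= 1, bar_thickness_px > 0,
    stripe_width_px > 0, diamond_pitch_px > 0, max_tilt_deg > 0,
    length(background_black) == 3, length(background_blue) == 3
  )
  if (bar_length_px > width_px) {
    stop("`bar_length_px` must not exceed `width_px`", call. = FALSE)
  }
  structure(
    list(
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      bar_length_px = as.integer(bar_length_px),
      bar_count = as.integer(bar_count),
      bar_thickness_px = as.integer(bar_thickness_px),
      stripe_width_px = as.integer(stripe_width_px),
      background_black = as.numeric(background_black),
      background_blue = as.numeric(background_blue),
      diamond_pitch_px = as.integer(diamond_pitch_px),
      max_tilt_deg = as.numeric(max_tilt_deg)
    ),
    class = "canvas_spec"
  )
}

#' Enumerate the stimulus grid
#'
#' Builds the full factorial grid of stimulus conditions: bar hue x diamond
#' width x diamond positional setting. The default grid is the 12 ring hues,
#' diamond widths 5-10 px and settings I/II, i.e. 144 combinations. Order is
#' deterministic: colour-major, then width, then setting.
#'
#' @param palette A tibble of hues as returned by [default_color_ring()].
#' @param widths Integer vector of diamond side widths in pixels.
#' @param settings Character vector drawn from `"I"`, `"II"`. Setting II is
#'   the mirror arrangement of setting I and flips the perceived tilt
#'   direction.
#' @param canvas A [canvas_spec()]; attached to the result as an attribute.
#' @return A tibble with one row per stimulus: `stimulus_id`, `color_name`,
#'   `ring_index`, `r`, `g`, `b`, `diamond_width_px`, `setting`.
#' @examples
#' grid <- enumerate_stimulus_grid()
#' nrow(grid) # 144
#' @export
enumerate_stimulus_grid <- function(palette = default_color_ring(),
                                    widths = 5:10,
                                    settings = c("I", "II"),
                                    canvas = canvas_spec()) {
  if (nrow(palette) == 0 || length(widths) == 0 || length(settings) == 0) {
    stop("grid factors must all be non-empty", call. = FALSE)
  }
  if (!all(settings %in% c("I", "II"))) {
    stop("`settings` must be drawn from \"I\", \"II\"", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    palette[, c("name", "ring_index", "r", "g", "b")],
    diamond_width_px = as.integer(widths),
    setting = settings
  )
  grid <- dplyr::rename(grid, color_name = "name")
  grid <- dplyr::mutate(
    grid,
    stimulus_id = sprintf(
      "%s_w%d_%s", gsub("[ -]", "", .data$color_name),
      .data$diamond_width_px, .data$setting
    ),
    .before = 1
  )
  attr(grid, "canvas") <- canvas
  grid
}

#' Render an illusion stimulus (horizontal bars)
#'
#' Renders one point of the stimulus grid with all four bars exactly
#' horizontal. The perceived tilt of such an image is entirely illusory.
#'
#' @param stimulus A one-row tibble from [enumerate_stimulus_grid()] (or any
#'   list with `color_name`, `r`, `g`, `b`, `diamond_width_px`, `setting`).
#' @param canvas A [canvas_spec()]; defaults to the one attached to the grid
#'   the row came from, else [canvas_spec()] defaults.
#' @param scene `"full"` renders the complete scene (striped background and
#'   diamonds); `"plain"` renders only the coloured bars on a black
#'   background, for ablating non-tilt image content.
#' @return A `grating_image`: an `height x width x 3` array of 8-bit channel
#'   values (stored as 0-255 numerics) with the stimulus parameters attached
#'   as attributes. Rendering is fully deterministic.
#' @export
render_illusion <- function(stimulus, canvas = NULL, scene = c("full", "plain")) {
  canvas <- resolve_canvas(stimulus, canvas)
  render_grating(stimulus, rep(0, canvas$bar_count), canvas, match.arg(scene))
}

#' Render a tilted-bar counterpart of a stimulus
#'
#' Same scene as [render_illusion()], but each bar (with its diamonds) is
#' rotated about its own centre by a per-bar angle; the striped background is
#' left unrotated. Angles are in degrees, clockwise-positive (the right end of
#' the bar moves down). A zero tilt reproduces [render_illusion()] exactly.
#'
#' @inheritParams render_illusion
#' @param tilt_deg Numeric vector of per-bar angles, degrees; length must
#'   equal the canvas bar count.
#' @return A `grating_image` array; see [render_illusion()].
#' @export
render_tilted <- function(stimulus, tilt_deg, canvas = NULL,
                          scene = c("full", "plain")) {
  canvas <- resolve_canvas(stimulus, canvas)
  if (length(tilt_deg) != canvas$bar_count) {
    stop("`tilt_deg` must give one angle per bar (", canvas$bar_count, ")",
      call. = FALSE
    )
  }
  if (any(!is.finite(tilt_deg))) stop("tilt angles must be finite", call. = FALSE)
  if (any(abs(tilt_deg) > canvas$max_tilt_deg)) {
    stop("tilt magnitude exceeds `max_tilt_deg` (", canvas$max_tilt_deg, " deg)",
      call. = FALSE
    )
  }
  render_grating(stimulus, tilt_deg, canvas, match.arg(scene))
}

resolve_canvas <- function(stimulus, canvas) {
  canvas <- canvas %||% attr(stimulus, "canvas") %||% canvas_spec()
  stopifnot(inherits(canvas, "canvas_spec"))
  canvas
}

# Core renderer. Shapes are composited with analytic ~1 px linear
# anti-aliasing, which keeps renders deterministic and exactly
# mirror-symmetric: flipping the canvas horizontally while negating the tilt
# and swapping setting I <-> II reproduces the same pixels.
render_grating <- function(stimulus, tilt_deg, canvas, scene = "full") {
  stim <- as.list(stimulus)
  w <- as.integer(stim$diamond_width_px)
  if (length(w) != 1 || is.na(w) || w < 1) {
    stop("`diamond_width_px` must be a positive integer", call. = FALSE)
  }
  half_diag <- w / sqrt(2)
  if (half_diag > canvas$bar_thickness_px) {
    stop("diamond width exceeds the bar thickness budget", call. = FALSE)
  }
  setting <- match.arg(stim$setting, c("I", "II"))
  bar_rgb <- c(stim$r, stim$g, stim$b) / 255

  W <- canvas$width_px
  H <- canvas$height_px
  px <- seq_len(W) - 0.5
  py <- seq_len(H) - 0.5
  cx <- W / 2

  img <- array(0, dim = c(H, W, 3))
  if (scene == "full") {
    # background: stripes indexed outward from the midline
    stripe_idx <- floor(abs(px - cx) / canvas$stripe_width_px)
    is_black <- stripe_idx %% 2 == 0
    bg_cols <- rbind(
      canvas$background_black / 255,
      canvas$background_blue / 255
    )[ifelse(is_black, 1L, 2L), , drop = FALSE]
    for (ch in 1:3) img[, , ch] <- matrix(bg_cols[, ch], H, W, byrow = TRUE)
  }

  # diamonds: centres at fixed pitch, symmetric about the bar centre; the
  # count is forced even so that mirroring the canvas swaps settings exactly
  pitch <- canvas$diamond_pitch_px
  n_dia <- floor(canvas$bar_length_px / pitch)
  n_dia <- n_dia - n_dia %% 2
  u_centres <- (seq_len(n_dia) - 0.5 - n_dia / 2) * pitch
  phase <- if (setting == "I") 0L else 1L

  half_th <- canvas$bar_thickness_px / 2
  half_len <- canvas$bar_length_px / 2
  bar_cy <- H * (seq_len(canvas$bar_count) - 0.5) / canvas$bar_count

  for (k in seq_len(canvas$bar_count)) {
    theta <- tilt_deg[k] * pi / 180
    ct <- cos(theta)
    st <- sin(theta)
    extent <- half_th + half_diag + abs(st) * half_len + 2
    rows <- which(abs(py - bar_cy[k]) <= extent)
    if (length(rows) == 0) next
    dy <- py[rows] - bar_cy[k]
    dx <- px - cx
    # rotated bar frame; clockwise-positive angle in screen coordinates
    u <- outer(dy * st, dx * ct, "+")
    v <- outer(dy * ct, -dx * st, "+")

    band <- img[rows, , , drop = FALSE]
    alpha <- clamp01(half_th - abs(v) + 0.5) * clamp01(half_len - abs(u) + 0.5)
    for (ch in 1:3) {
      band[, , ch] <- band[, , ch] * (1 - alpha) + bar_rgb[ch] * alpha
    }

    if (scene == "plain") {
      img[rows, , ] <- band
      next
    }
    for (edge in c(-1, 1)) {
      v0 <- edge * half_th
      for (j in seq_len(n_dia)) {
        # top edge: black on (j + phase) even; bottom edge: the complement
        black <- ((j + phase) %% 2 == 0) == (edge < 0)
        dcol <- if (black) 0 else 1
        margin <- half_diag + abs(st) * (extent + 1) + 2
        jr <- which(dx >= u_centres[j] - margin & dx <= u_centres[j] + margin)
        if (length(jr) == 0) next
        du <- abs(u[, jr, drop = FALSE] - u_centres[j])
        dv <- abs(v[, jr, drop = FALSE] - v0)
        a <- clamp01(0.5 + (half_diag - (du + dv)) / sqrt(2))
        for (ch in 1:3) {
          band[, jr, ch] <- band[, jr, ch] * (1 - a) + dcol * a
        }
      }
    }
    img[rows, , ] <- band
  }

  img <- round(img * 255)
  structure(
    img,
    class = "grating_image",
    color_name = stim$color_name,
    rgb = c(stim$r, stim$g, stim$b),
    diamond_width_px = w,
    setting = setting,
    tilt_deg = tilt_deg,
    scene = scene,
    canvas = canvas
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Downscale a rendered image by block averaging
#'
#' @param img A `grating_image` (or plain numeric array) on the 0-255 scale.
#' @param factor Integer downscale factor; canvas dimensions must be
#'   divisible by it.
#' @return A numeric array of the reduced size, still on the 0-255 scale.
#' @export
downscale_image <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  d <- dim(img)
  if (factor == 1L) return(unclass(img))
  if (any(d[1:2] %% factor != 0)) {
    stop("image dimensions must be divisible by `factor`", call. = FALSE)
  }
  h2 <- d[1] %/% factor
  w2 <- d[2] %/% factor
  out <- array(0, dim = c(h2, w2, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    m <- rowsum(m, group = rep(seq_len(h2), each = factor))
    m <- t(rowsum(t(m), group = rep(seq_len(w2), each = factor)))
    out[, , ch] <- m / factor^2
  }
  out
}

#' Write a rendered stimulus to PNG (with a JSON sidecar)
#'
#' @param img A `grating_image`.
#' @param path Output PNG path.
#' @param sidecar Write `<path>.json` recording the full stimulus parameters?
#' @return `path`, invisibly.
#' @export
write_grating_png <- function(img, path, sidecar = TRUE) {
  png::writePNG(unclass(img) / 255, target = path)
  if (sidecar) {
    meta <- list(
      color_name = attr(img, "color_name"),
      rgb = attr(img, "rgb"),
      diamond_width_px = attr(img, "diamond_width_px"),
      setting = attr(img, "setting"),
      tilt_deg = attr(img, "tilt_deg"),
      canvas = unclass(attr(img, "canvas"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @importFrom rlang %||% .data
NULL
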