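#' The default 12-hue RGB colour ring
#'
#' The bar colours of the oblique-grating stimulus grid are the 12 hues of the
#' RGB colour ring sampled every 30 degrees at full saturation and full value.
#' Hue names follow the conventional names for those ring positions (red at
#' 0 degrees through rose at 330 degrees).
#'
#' @return A tibble with one row per hue and columns `name`, `ring_index`
#'   (0-11, ordered by hue angle), `hue_deg`, `r`, `g`, `b` (8-bit channel
#'   values) and `hex`.
#' @examples
#' default_color_ring()
#' @export
default_color_ring <- function() {
  names <- c(
    "red", "orange", "yellow", "yellow-green", "green", "spring green",
    "cyan", "dodger blue", "blue", "violet", "magenta", "rose"
  )
  hue <- 30 * (seq_along(names) - 1)
  rgb <- t(vapply(hue, hsv_to_rgb255, numeric(3)))
  tibble::tibble(
    name = names,
    ring_index = seq_along(names) - 1L,
    hue_deg = hue,
    r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
    hex = grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  )
}

# HSV (s = v = 1) -> rounded 8-bit RGB for a hue angle in degrees.
hsv_to_rgb255 <- function(h, s = 1, v = 1) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  rgb01 <- switch(as.character(i %% 6),
    "0" = c(v, t, p),
    "1" = c(q, v, p),
    "2" = c(p, v, t),
    "3" = c(p, q, v),
    "4" = c(t, p, v),
    "5" = c(v, p, q)
  )
  as.numeric(round(255 * rgb01))
}
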