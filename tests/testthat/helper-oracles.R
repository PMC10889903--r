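# Shared fixtures and independent oracle implementations used across tests.

# A reduced stimulus grid (2 hues x 2 widths x 2 settings) for fast tests.
small_grid <- function() {
  pal <- default_color_ring()
  enumerate_stimulus_grid(
    palette = pal[pal$name %in% c("red", "green"), ],
    widths = c(5L, 9L)
  )
}

# Render a manifest at a coarse resolution for fast training tests.
render_small <- function(manifest, downscale = 4L) {
  render_manifest(manifest, downscale = downscale)
}

# Naive-loop Grad-CAM oracle: independent of the package implementation.
oracle_gradcam <- function(activations, gradients) {
  d <- dim(activations)
  alpha <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) {
      for (j in seq_len(d[2])) {
        s <- s + gradients[i, j, k]
      }
    }
    alpha[k] <- s / (d[1] * d[2])
  }
  L <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      acc <- 0
      for (k in seq_len(d[3])) {
        acc <- acc + alpha[k] * activations[i, j, k]
      }
      L[i, j] <- max(acc, 0)
    }
  }
  list(alpha = alpha, map = L)
}

# Brute-force elementwise distance oracle.
oracle_distance <- function(a, b, mode) {
  av <- as.numeric(a)
  bv <- as.numeric(b)
  s <- 0
  for (i in seq_along(av)) s <- s + (av[i] - bv[i])^2
  if (mode == "euclidean") sqrt(s) else s
}

# Threshold oracle for strength -> level -> class, written as an explicit
# scan over the eight bin upper edges (left-open, right-closed bins).
oracle_level <- function(s) {
  edges <- (1:8) * 0.1
  for (k in 1:8) {
    if (s <= edges[k] + 1e-9) return(k)
  }
  8L
}

# Moment-based principal-axis orientation estimate (degrees,
# clockwise-positive in screen coordinates where y grows downward).
oracle_bar_angle <- function(img, canvas, bar_k) {
  lum <- (unclass(img)[, , 1] + unclass(img)[, , 2] + unclass(img)[, , 3]) / 3
  H <- canvas$height_px
  cy <- H * (bar_k - 0.5) / canvas$bar_count
  rows <- which(abs(seq_len(H) - 0.5 - cy) <= H / (2 * canvas$bar_count))
  m <- lum[rows, ]
  xs <- seq_len(ncol(m)) - 0.5
  ys <- seq_along(rows) - 0.5
  w <- m / sum(m)
  mx <- sum(colSums(w) * xs)
  my <- sum(rowSums(w) * ys)
  X <- matrix(xs - mx, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys - my, length(ys), length(xs))
  sxx <- sum(w * X * X)
  syy <- sum(w * Y * Y)
  sxy <- sum(w * X * Y)
  # principal axis of the intensity distribution; y is downward, so a
  # positive angle means the right end of the bar sits lower
  0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
}
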