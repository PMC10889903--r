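#' Gradient-weighted class-activation weights
#'
#' For class score `y_c` and feature maps `A^k` at a tapped layer, the
#' per-map weight is the spatial mean of the gradient:
#' `alpha_k = (1/Z) * sum_ij d y_c / d A_ij^k`, with `Z` the number of
#' spatial positions.
#'
#' @param activations `H x W x K` array of feature-map activations.
#' @param gradients Array of the same shape holding `d y_c / d A^k`.
#' @return A list of class `gradcam_weights` with `alpha` (length `K`) and
#'   `Z`.
#' @export
gradcam_weights <- function(activations, gradients) {
  da <- dim(activations)
  if (is.null(da) || length(da) != 3 || !identical(da, dim(gradients))) {
    stop("activations and gradients must be H x W x K arrays of equal shape",
      call. = FALSE
    )
  }
  structure(
    list(
      alpha = apply(gradients, 3, mean),
      Z = da[1] * da[2]
    ),
    class = "gradcam_weights"
  )
}

#' Class-activation localization map
#'
#' The map is the rectified weighted combination of the forward activations:
#' `L_ij = ReLU(sum_k alpha_k * A_ij^k)`; rectification keeps only the
#' evidence that argues for the class.
#'
#' @param weights A [gradcam_weights()] object (or bare numeric `alpha`).
#' @param activations `H x W x K` activation array.
#' @return A non-negative `H x W` matrix of class `heatmap`.
#' @export
gradcam_map <- function(weights, activations) {
  alpha <- if (inherits(weights, "gradcam_weights")) weights$alpha else weights
  da <- dim(activations)
  if (is.null(da) || length(da) != 3 || length(alpha) != da[3]) {
    stop("need one weight per feature map", call. = FALSE)
  }
  L <- matrix(0, da[1], da[2])
  for (k in seq_len(da[3])) {
    L <- L + alpha[k] * activations[, , k]
  }
  L[L < 0] <- 0
  structure(L, class = c("heatmap", "matrix"))
}

#' Grad-CAM for a rendered stimulus
#'
#' Runs the forward pass, takes the gradient of the requested class logit
#' with respect to the tapped activations, and combines them into a
#' localization map.
#'
#' @param model A trained `desknet` model.
#' @param image A `grating_image`.
#' @param class `"C1"` or `"C2"`; the class whose evidence is localized.
#' @param layer Tap name (default the last convolutional block).
#' @param downscale Downscale factor applied to the image before the forward
#'   pass; use the factor the model was trained at.
#' @return A `heatmap` with attributes `layer_id`, `class_id` and the
#'   model's `logits` for the image.
#' @export
gradcam <- function(model, image, class = c("C2", "C1"), layer = NULL,
                    downscale = 2L) {
  class <- match.arg(class)
  layer <- layer %||% model$taps[length(model$taps)]
  tap_idx <- match(layer, model$taps)
  if (is.na(tap_idx)) {
    stop("unknown layer: ", layer, "; taps are ",
      paste(model$taps, collapse = ", "),
      call. = FALSE
    )
  }
  img <- if (downscale > 1L) downscale_image(image, downscale) else unclass(image)
  x <- image_to_input(img)
  h <- dim(img)[1]
  w <- dim(img)[2]
  fwd <- dn_taps(model$params, model$arch, x, h, w)
  grad <- dn_tap_grad(
    model$params, model$arch, x, h, w,
    if (class == "C2") 1L else 0L, tap_idx
  )
  acts <- fwd$taps[[tap_idx]]
  map <- gradcam_map(gradcam_weights(acts, grad), acts)
  attr(map, "layer_id") <- layer
  attr(map, "class_id") <- class
  attr(map, "logits") <- fwd$logits
  map
}

#' Overlay a heatmap on its source image
#'
#' The map is min-max normalized (a flat map, including all-zero, becomes a
#' uniform mid-level wash and is flagged in the `flat` attribute), bilinearly
#' upsampled to the image size, mapped through a colour ramp and
#' alpha-blended onto the image.
#'
#' @param map A `heatmap`.
#' @param image The `grating_image` it was computed from.
#' @param alpha Blend weight of the heatmap colour, in (0, 1).
#' @param ramp Colour ramp, passed to [grDevices::colorRamp()].
#' @return A `grating_image`-like 0-255 array with attribute `flat`.
#' @export
heatmap_overlay <- function(map, image, alpha = 0.45,
                            ramp = c("navy", "blue", "cyan", "yellow", "red")) {
  stopifnot(alpha > 0, alpha < 1)
  m <- unclass(map)
  rng <- range(m)
  flat <- diff(rng) <= 0
  norm <- if (flat) matrix(0.5, nrow(m), ncol(m)) else (m - rng[1]) / diff(rng)
  d <- dim(image)
  up <- resize_bilinear(norm, d[1], d[2])
  cols <- grDevices::colorRamp(ramp)(as.vector(up)) # n x 3, 0-255
  out <- array(0, dim = d)
  for (ch in 1:3) {
    out[, , ch] <- (1 - alpha) * unclass(image)[, , ch] +
      alpha * matrix(cols[, ch], d[1], d[2])
  }
  out <- round(out)
  attr(out, "flat") <- flat
  attr(out, "layer_id") <- attr(map, "layer_id")
  attr(out, "class_id") <- attr(map, "class_id")
  class(out) <- "grating_image"
  out
}

# Bilinear resampling of a matrix to a target size (align-corners = FALSE).
resize_bilinear <- function(m, h_out, w_out) {
  h_in <- nrow(m)
  w_in <- ncol(m)
  sy <- h_in / h_out
  sx <- w_in / w_out
  yi <- pmin(pmax((seq_len(h_out) - 0.5) * sy - 0.5, 0), h_in - 1)
  xi <- pmin(pmax((seq_len(w_out) - 0.5) * sx - 0.5, 0), w_in - 1)
  y0 <- pmin(floor(yi), h_in - 1)
  x0 <- pmin(floor(xi), w_in - 1)
  y1 <- pmin(y0 + 1, h_in - 1)
  x1 <- pmin(x0 + 1, w_in - 1)
  fy <- yi - y0
  fx <- xi - x0
  a <- m[cbind(rep(y0 + 1, w_out), rep(x0 + 1, each = h_out))]
  b <- m[cbind(rep(y0 + 1, w_out), rep(x1 + 1, each = h_out))]
  cc <- m[cbind(rep(y1 + 1, w_out), rep(x0 + 1, each = h_out))]
  d <- m[cbind(rep(y1 + 1, w_out), rep(x1 + 1, each = h_out))]
  wfy <- rep(fy, w_out)
  wfx <- rep(fx, each = h_out)
  v <- a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
    cc * wfy * (1 - wfx) + d * wfy * wfx
  matrix(v, h_out, w_out)
}
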