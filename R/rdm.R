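#' Extract tapped feature maps for one image
#'
#' Runs a forward pass and returns the post-ReLU activations of one tapped
#' convolutional block.
#'
#' @param model A `desknet` model.
#' @param image A `grating_image`.
#' @param layer Tap name (e.g. `"conv1"`); defaults to the last tap.
#' @param downscale Downscale factor applied before the forward pass; use
#'   the factor the model was trained at.
#' @return An `H x W x K` array with attribute `layer_id`.
#' @export
extract_features <- function(model, image, layer = NULL, downscale = 2L) {
  layer <- layer %||% model$taps[length(model$taps)]
  tap_idx <- match(layer, model$taps)
  if (is.na(tap_idx)) {
    stop("unknown layer: ", layer, "; taps are ",
      paste(model$taps, collapse = ", "),
      call. = FALSE
    )
  }
  img <- if (downscale > 1L) downscale_image(image, downscale) else unclass(image)
  fwd <- dn_taps(model$params, model$arch, image_to_input(img),
    dim(img)[1], dim(img)[2]
  )
  feats <- fwd$taps[[tap_idx]]
  attr(feats, "layer_id") <- layer
  feats
}

#' Distance between two feature tensors
#'
#' The base quantity is the summed squared elementwise difference
#' `r = sum((a - b)^2)`. `mode = "euclidean"` (the default) reports
#' `sqrt(r)`; `mode = "sq_sum"` reports `r` itself.
#'
#' @param a,b Numeric arrays of identical shape.
#' @param mode `"euclidean"` or `"sq_sum"`.
#' @return A single non-negative number.
#' @export
pair_distance <- function(a, b, mode = c("euclidean", "sq_sum")) {
  mode <- match.arg(mode)
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("feature tensors must have identical shape", call. = FALSE)
  }
  r <- sum((as.numeric(a) - as.numeric(b))^2)
  if (mode == "euclidean") sqrt(r) else r
}

#' Select one exemplar stimulus per illusion-strength level
#'
#' For each level `k` in 1..8, picks the grid stimulus whose aggregated
#' strength is nearest the bin centre `(k - 0.5) * 0.1` degrees (ties broken
#' by `stimulus_id`). A level's exemplar is the closest available stimulus
#' even if that stimulus's own strength falls in a neighbouring bin, so
#' sparsely populated levels still get a representative.
#'
#' @param strengths Per-stimulus tibble from [aggregate_strengths()].
#' @return An 8-row tibble: `level`, `bin_center_deg`, `stimulus_id`,
#'   `strength_deg` and the signed `mean_angle1`-`mean_angle4` used for the
#'   perceived-tilt render.
#' @export
select_level_exemplars <- function(strengths) {
  needed <- c("stimulus_id", "strength_deg", paste0("mean_angle", 1:4))
  missing <- setdiff(needed, names(strengths))
  if (length(missing) > 0) {
    stop("strengths lack columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  ord <- strengths[order(strengths$stimulus_id), ]
  purrr::map_dfr(1:8, function(k) {
    center <- (k - 0.5) * 0.1
    i <- which.min(abs(ord$strength_deg - center))
    tibble::tibble(
      level = k,
      bin_center_deg = center,
      stimulus_id = ord$stimulus_id[i],
      strength_deg = ord$strength_deg[i],
      mean_angle1 = ord$mean_angle1[i],
      mean_angle2 = ord$mean_angle2[i],
      mean_angle3 = ord$mean_angle3[i],
      mean_angle4 = ord$mean_angle4[i]
    )
  })
}

#' Cross-set representational dissimilarity matrix
#'
#' Compares two image sets at one tapped layer: the "perceived" set
#' (exemplars rendered with the bar tilts humans adjusted to, i.e. the mean
#' reported angles) and the "real" set (the same exemplars rendered with
#' physically horizontal bars). Entry `(i, j)` is the feature-space distance
#' `r` between perceived exemplar `i` and real exemplar `j`; the normalized
#' matrix is `R = r / mean(r)`, so `mean(R) = 1` regardless of layer scale
#' and values above 1 mark pairs the layer separates more than average.
#'
#' @param perceived,real Lists of `grating_image`s of equal length (one per
#'   level), in level order.
#' @param model A trained `desknet` model.
#' @param layer Tap name.
#' @param mode Distance mode, see [pair_distance()].
#' @param downscale Downscale factor for the forward pass.
#' @return A `cross_rdm`: list with raw `r`, normalized `R` (both
#'   `n x n`, rows = perceived, cols = real), `layer_id`, `mode`, `levels`.
#' @export
build_cross_rdm <- function(perceived, real, model, layer = NULL,
                            mode = c("euclidean", "sq_sum"), downscale = 2L) {
  mode <- match.arg(mode)
  if (length(perceived) != length(real) || length(perceived) == 0) {
    stop("perceived and real must be non-empty lists of equal length",
      call. = FALSE
    )
  }
  fp <- lapply(perceived, extract_features, model = model, layer = layer,
    downscale = downscale
  )
  fr <- lapply(real, extract_features, model = model, layer = layer,
    downscale = downscale
  )
  n <- length(fp)
  r <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r[i, j] <- pair_distance(fp[[i]], fr[[j]], mode = mode)
    }
  }
  m <- mean(r)
  R <- if (m > 0) r / m else matrix(1, n, n)
  structure(
    list(
      r = r, R = R,
      layer_id = attr(fp[[1]], "layer_id"),
      mode = mode,
      levels = seq_len(n)
    ),
    class = "cross_rdm"
  )
}

#' Per-layer cross-set RDMs for the level exemplars
#'
#' Convenience wrapper: selects one exemplar per level, renders its
#' perceived-tilt and horizontal versions once, and builds a [build_cross_rdm()]
#' matrix at each requested tap.
#'
#' @param model A trained `desknet` model.
#' @param strengths Per-stimulus tibble from [aggregate_strengths()].
#' @param grid Stimulus grid the exemplars come from.
#' @param layers Tap names (default all taps, shallow to deep).
#' @inheritParams build_cross_rdm
#' @return A named list of `cross_rdm`, one per layer, with the exemplar
#'   table attached as attribute `exemplars`.
#' @export
cross_rdm_stack <- function(model, strengths,
                            grid = enumerate_stimulus_grid(),
                            layers = model$taps,
                            mode = c("euclidean", "sq_sum"),
                            downscale = 2L) {
  mode <- match.arg(mode)
  canvas <- attr(grid, "canvas") %||% canvas_spec()
  ex <- select_level_exemplars(strengths)
  idx <- match(ex$stimulus_id, grid$stimulus_id)
  if (any(is.na(idx))) {
    stop("exemplar stimuli not found in grid", call. = FALSE)
  }
  perceived <- lapply(seq_len(nrow(ex)), function(i) {
    render_tilted(
      grid[idx[i], ],
      c(ex$mean_angle1[i], ex$mean_angle2[i], ex$mean_angle3[i], ex$mean_angle4[i]),
      canvas
    )
  })
  real <- lapply(idx, function(i) render_illusion(grid[i, ], canvas))
  out <- lapply(layers, function(l) {
    build_cross_rdm(perceived, real, model,
      layer = l, mode = mode, downscale = downscale
    )
  })
  names(out) <- layers
  attr(out, "exemplars") <- ex
  out
}

#' Perceived-vs-real distance by network depth
#'
#' For every grid stimulus, measures the feature-space distance between its
#' horizontal render and its perceived-tilt render at each tapped layer, and
#' summarises by depth within strata defined by the model's illusion-test
#' verdict (correct / incorrect) and the human-derived class (C1 / C2).
#' Strata with no members are omitted.
#'
#' @param model A trained `desknet` model.
#' @param strengths Per-stimulus tibble from [aggregate_strengths()].
#' @param grid Stimulus grid.
#' @param layers Tap names (default all taps).
#' @param mode Distance mode, see [pair_distance()].
#' @param downscale Downscale factor for the forward passes.
#' @return A tibble: `layer_id`, `illusion_class`, `correct`,
#'   `mean_distance`, `n`.
#' @export
depth_profile <- function(model, strengths,
                          grid = enumerate_stimulus_grid(),
                          layers = model$taps,
                          mode = c("euclidean", "sq_sum"),
                          downscale = 2L) {
  mode <- match.arg(mode)
  canvas <- attr(grid, "canvas") %||% canvas_spec()
  idx <- match(grid$stimulus_id, strengths$stimulus_id)
  if (any(is.na(idx))) {
    stop("strengths must cover every grid stimulus", call. = FALSE)
  }
  tap_ix <- match(layers, model$taps)
  if (any(is.na(tap_ix))) {
    stop("unknown layer(s): ", paste(layers[is.na(tap_ix)], collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(grid)
  dist <- matrix(0, n, length(layers))
  pred <- character(n)
  for (i in seq_len(n)) {
    st <- strengths[idx[i], ]
    real <- render_illusion(grid[i, ], canvas)
    perc <- render_tilted(
      grid[i, ],
      c(st$mean_angle1, st$mean_angle2, st$mean_angle3, st$mean_angle4),
      canvas
    )
    ri <- if (downscale > 1L) downscale_image(real, downscale) else unclass(real)
    pi_ <- if (downscale > 1L) downscale_image(perc, downscale) else unclass(perc)
    fr <- dn_taps(model$params, model$arch, image_to_input(ri),
      dim(ri)[1], dim(ri)[2]
    )
    fp <- dn_taps(model$params, model$arch, image_to_input(pi_),
      dim(pi_)[1], dim(pi_)[2]
    )
    for (l in seq_along(layers)) {
      dist[i, l] <- pair_distance(
        fp$taps[[tap_ix[l]]], fr$taps[[tap_ix[l]]],
        mode = mode
      )
    }
    pred[i] <- if (fr$logits[2] > fr$logits[1]) "C2" else "C1"
  }
  truth <- as.character(strengths$illusion_class[idx])
  per_stim <- tibble::tibble(
    stimulus_id = grid$stimulus_id,
    illusion_class = truth,
    correct = pred == truth
  )
  out <- purrr::map_dfr(seq_along(layers), function(l) {
    d <- per_stim
    d$layer_id <- layers[l]
    d$distance <- dist[, l]
    d
  })
  dplyr::summarise(
    dplyr::group_by(out, .data$layer_id, .data$illusion_class, .data$correct),
    mean_distance = mean(.data$distance),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Combined saliency + representation framework score
#'
#' Reduces a pair of class heatmaps and a per-layer RDM stack to a single
#' scalar. Under the `"diag_contrast_minus_spread"` synthesis:
#' * `rdm_summary` is the mean off-diagonal minus the mean diagonal of the
#'   normalized RDM at the earliest (first-listed) layer - positive when
#'   matched perceived/real levels are closer than mismatched ones;
#' * `gradcam_summary` is the mean absolute difference between the
#'   min-max-normalized C1 and C2 maps - how differently the two classes
#'   allocate spatial evidence;
#' * the score is their weighted sum.
#'
#' @param heatmaps A list with elements `C1` and `C2`, each a `heatmap` of
#'   identical shape.
#' @param rdms A named list of `cross_rdm` (e.g. from [cross_rdm_stack()]),
#'   ordered shallow to deep; or a single `cross_rdm`.
#' @param weights Named weights `c(rdm = , gradcam = )`.
#' @param synthesis Synthesis rule; only `"diag_contrast_minus_spread"` is
#'   defined, anything else errors.
#' @return A `framework_score` list: `score`, `rdm_summary`,
#'   `gradcam_summary`, `weights`, `layer_id`, `synthesis`.
#' @export
framework_score <- function(heatmaps, rdms,
                            weights = c(rdm = 0.5, gradcam = 0.5),
                            synthesis = "diag_contrast_minus_spread") {
  if (!identical(synthesis, "diag_contrast_minus_spread")) {
    stop("unknown synthesis rule: ", synthesis, call. = FALSE)
  }
  if (!all(c("rdm", "gradcam") %in% names(weights))) {
    stop("weights must be named c(rdm = , gradcam = )", call. = FALSE)
  }
  if (inherits(rdms, "cross_rdm")) rdms <- list(rdms)
  if (length(rdms) == 0 || !inherits(rdms[[1]], "cross_rdm")) {
    stop("rdms must be one or more cross_rdm objects", call. = FALSE)
  }
  if (!all(c("C1", "C2") %in% names(heatmaps))) {
    stop("heatmaps must have elements C1 and C2", call. = FALSE)
  }
  R <- rdms[[1]]$R
  off <- R[row(R) != col(R)]
  rdm_summary <- mean(off) - mean(diag(R))

  norm01 <- function(m) {
    m <- unclass(m)
    rng <- range(m)
    if (diff(rng) <= 0) matrix(0.5, nrow(m), ncol(m)) else (m - rng[1]) / diff(rng)
  }
  h1 <- norm01(heatmaps$C1)
  h2 <- norm01(heatmaps$C2)
  if (!identical(dim(h1), dim(h2))) {
    stop("C1 and C2 heatmaps must have the same shape", call. = FALSE)
  }
  gradcam_summary <- mean(abs(h1 - h2))

  structure(
    list(
      score = unname(weights["rdm"] * rdm_summary +
        weights["gradcam"] * gradcam_summary),
      rdm_summary = rdm_summary,
      gradcam_summary = gradcam_summary,
      weights = weights,
      layer_id = rdms[[1]]$layer_id,
      synthesis = synthesis
    ),
    class = "framework_score"
  )
}

#' @export
print.cross_rdm <- function(x, ...) {
  cat("<cross_rdm> layer ", x$layer_id, ", mode ", x$mode,
    ", ", nrow(x$R), "x", ncol(x$R),
    " (rows perceived, cols real), mean(R) = ",
    format(mean(x$R), digits = 4), "\n",
    sep = ""
  )
  print(round(x$R, 3))
  invisible(x)
}

#' @export
print.framework_score <- function(x, ...) {
  cat(
    "<framework_score> ", format(x$score, digits = 4),
    "  (rdm ", format(x$rdm_summary, digits = 4),
    " @ ", x$layer_id,
    ", gradcam ", format(x$gradcam_summary, digits = 4),
    "; weights rdm=", x$weights[["rdm"]],
    " gradcam=", x$weights[["gradcam"]], ")\n",
    sep = ""
  )
  invisible(x)
}
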