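#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report into one row per cell of the confusion matrix
#'
#' @param x A `metrics_report` from [evaluate()].
#' @param ... Unused.
#' @return A tibble with `truth`, `prediction`, `n` and `fraction` (of the
#'   truth row).
#' @export
tidy.metrics_report <- function(x, ...) {
  cm <- x$confusion
  out <- tibble::tibble(
    truth = rep(rownames(cm), times = ncol(cm)),
    prediction = rep(colnames(cm), each = nrow(cm)),
    n = as.integer(as.vector(cm))
  )
  row_n <- rowSums(cm)[out$truth]
  out$fraction <- ifelse(row_n > 0, out$n / row_n, NA_real_)
  out
}

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `accuracy`, `recall`, `precision`, `f1`.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, accuracy = x$accuracy, recall = x$recall,
    precision = x$precision, f1 = x$f1
  )
}

#' Tidy a permutation result into one row per permutation
#'
#' @param x A `permutation_result` from [permutation_test()].
#' @param ... Unused.
#' @return A tibble with `permutation` and `null_accuracy`.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(
    permutation = seq_along(x$null_accuracies),
    null_accuracy = x$null_accuracies
  )
}

#' One-row summary of a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_perms`, `actual_accuracy`, the null
#'   percentile baseline and `significant`.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    n_perms = x$n_perms,
    actual_accuracy = x$actual_accuracy,
    percentile = x$percentile,
    null_percentile = x$percentile95,
    significant = x$significant
  )
}

#' Tidy a cross-set RDM into one row per cell
#'
#' @param x A `cross_rdm` from [build_cross_rdm()].
#' @param ... Unused.
#' @return A tibble with `perceived_level`, `real_level`, raw distance `r`
#'   and normalized `R`.
#' @export
tidy.cross_rdm <- function(x, ...) {
  n <- length(x$levels)
  tibble::tibble(
    perceived_level = rep(x$levels, times = n),
    real_level = rep(x$levels, each = n),
    r = as.vector(x$r),
    R = as.vector(x$R)
  )
}

#' One-row summary of a cross-set RDM
#'
#' @param x A `cross_rdm`.
#' @param ... Unused.
#' @return A one-row tibble: `layer_id`, `mode`, mean diagonal and mean
#'   off-diagonal of the normalized matrix, and their difference
#'   (`diag_contrast`, positive when matched levels are closer).
#' @export
glance.cross_rdm <- function(x, ...) {
  R <- x$R
  d <- mean(diag(R))
  o <- mean(R[row(R) != col(R)])
  tibble::tibble(
    layer_id = x$layer_id, mode = x$mode,
    mean_diag = d, mean_offdiag = o, diag_contrast = o - d
  )
}

#' Tidy a trained model's training log
#'
#' @param x A `desknet` model.
#' @param ... Unused.
#' @return The per-epoch log tibble (empty for untrained models).
#' @export
tidy.desknet <- function(x, ...) {
  x$log %||% tibble::tibble(
    epoch = integer(), lr = double(),
    train_loss = double(), train_accuracy = double(),
    val_loss = double(), val_accuracy = double()
  )
}

#' One-row summary of a model
#'
#' @param x A `desknet` model.
#' @param ... Unused.
#' @return A one-row tibble: architecture, parameter count, trained flag and
#'   final epoch accuracies (NA when untrained).
#' @export
glance.desknet <- function(x, ...) {
  last <- if (!is.null(x$log) && nrow(x$log) > 0) {
    x$log[nrow(x$log), ]
  } else {
    tibble::tibble(train_accuracy = NA_real_, val_accuracy = NA_real_)
  }
  tibble::tibble(
    arch = x$arch_name,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    trained = isTRUE(x$trained),
    train_accuracy = last$train_accuracy,
    val_accuracy = last$val_accuracy
  )
}
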