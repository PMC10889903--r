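#' Training hyperparameters
#'
#' Defaults follow the fine-tuning recipe used throughout the analyses:
#' Adam, initial learning rate 0.001 multiplied by 0.9 every five epochs
#' ("reduced by 10%"), weight decay, softmax cross-entropy. The full-scale
#' setting trains for 100 epochs; the desk-scale default is 10.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied every
#'   `lr_decay_every` epochs; the learning rate at epoch `e` (1-based) is
#'   `initial_lr * lr_decay_factor^floor(e / lr_decay_every)`.
#' @param lr_decay_every Epoch interval between decays.
#' @param epochs Number of training epochs.
#' @param optimizer Only `"adam"` is implemented.
#' @param weight_decay L2 penalty on weight matrices (biases excluded).
#' @param dropout_rate Dropout probability on the global-average-pooled
#'   features during training; 0 disables.
#' @param batch_size Minibatch size.
#' @param seed Global seed; fans out to weight initialization, epoch
#'   shuffling and dropout draws.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(initial_lr = 0.001, lr_decay_factor = 0.9,
                        lr_decay_every = 5L, epochs = 10L,
                        optimizer = "adam", weight_decay = 1e-4,
                        dropout_rate = 0, batch_size = 32L, seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(
    initial_lr > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
    lr_decay_every >= 1, epochs >= 1, weight_decay >= 0,
    dropout_rate >= 0, dropout_rate < 1, batch_size >= 1
  )
  structure(
    list(
      initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
      lr_decay_every = as.integer(lr_decay_every),
      epochs = as.integer(epochs), optimizer = optimizer,
      weight_decay = weight_decay, dropout_rate = dropout_rate,
      batch_size = as.integer(batch_size), seed = as.integer(seed)
    ),
    class = "hyperparams"
  )
}

#' The learning rate at a given epoch
#'
#' @param hp A [hyperparams()] object.
#' @param epoch 1-based epoch number(s).
#' @return Numeric learning rate(s):
#'   `initial_lr * lr_decay_factor^floor(epoch / lr_decay_every)`.
#' @export
lr_schedule <- function(hp, epoch) {
  hp$initial_lr * hp$lr_decay_factor^(epoch %/% hp$lr_decay_every)
}

#' Construct a classifier from the model registry
#'
#' The registry holds `"desknet"`, a compact CPU-scale CNN: four 3x3
#' convolution blocks (ReLU; strided in the first two blocks, 2x2 max-pooled
#' in the last two), global average pooling and a 2-way linear head. Two
#' fixed coordinate channels (normalized x and y) are appended to the RGB
#' input: sub-degree bar tilt displaces a bar vertically in proportion to the
#' horizontal distance from its centre, so making position explicit lets a
#' small network resolve the position-dependent signal. Every block exposes a
#' named activation tap (`conv1`-`conv4`) for class-activation mapping and
#' representational analysis.
#'
#' @param arch Architecture name; only `"desknet"` is registered.
#' @param pretrained Must be `FALSE`: no pretrained weights ship with the
#'   registry.
#' @param channels Integer vector of per-block output channels.
#' @param seed Seed for He-normal weight initialization.
#' @return A model object of class `desknet` exposing forward passes
#'   ([predict.desknet()]), taps ([extract_features()]) and gradients.
#' @export
make_model <- function(arch = "desknet", pretrained = FALSE,
                       channels = c(12L, 16L, 16L, 16L), seed = 1L) {
  if (!identical(arch, "desknet")) {
    stop("unknown architecture: ", arch, call. = FALSE)
  }
  if (isTRUE(pretrained)) {
    stop("no pretrained weights are available for the registry models",
      call. = FALSE
    )
  }
  stopifnot(length(channels) == 4, all(channels >= 1))
  spec <- list(
    channels = as.integer(channels),
    strides = c(2L, 2L, 1L, 1L),
    pools = c(0L, 0L, 1L, 1L),
    in_ch = 3L,
    coords = TRUE
  )
  model <- structure(
    list(
      arch_name = arch,
      arch = spec,
      taps = paste0("conv", seq_along(channels)),
      params = init_desknet_params(spec, seed),
      trained = FALSE,
      log = NULL
    ),
    class = "desknet"
  )
  model
}

init_desknet_params <- function(spec, seed) {
  with_seed(seed, {
    p <- list()
    cin <- spec$in_ch + if (spec$coords) 2L else 0L
    for (b in seq_along(spec$channels)) {
      cout <- spec$channels[b]
      fan_in <- cin * 9L
      p[[paste0("W", b)]] <- matrix(
        stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in
      )
      p[[paste0("b", b)]] <- numeric(cout)
      cin <- cout
    }
    p$Wd <- matrix(stats::rnorm(2 * cin, sd = sqrt(1 / cin)), 2, cin)
    p$bd <- numeric(2)
    p
  })
}

#' @export
print.desknet <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(
    "<desknet> 4 conv blocks (", paste(x$arch$channels, collapse = "-"),
    " channels), ", n_par, " parameters, ",
    if (x$trained) "trained" else "untrained", "\n",
    sep = ""
  )
  invisible(x)
}

#' Train a classifier on a rendered dataset
#'
#' Minimizes softmax cross-entropy with Adam under the stepped
#' learning-rate schedule of [hyperparams()]. Weights are (re-)initialized
#' from `hp$seed`, which also drives epoch shuffling and dropout, so runs
#' are reproducible.
#'
#' @param model A model from [make_model()].
#' @param train_set,val_set `grating_dataset` objects from
#'   [render_manifest()]; `val_set` may be `NULL`.
#' @param hp A [hyperparams()] object.
#' @param quiet Suppress the per-epoch progress line?
#' @return The trained model, with the per-epoch log (epoch, lr, losses,
#'   accuracies) in `$log`.
#' @export
train <- function(model, train_set, val_set = NULL, hp = hyperparams(),
                  quiet = TRUE) {
  stopifnot(inherits(model, "desknet"), inherits(hp, "hyperparams"))
  if (!inherits(train_set, "grating_dataset") || nrow(train_set$x) == 0) {
    stop("`train_set` must be a non-empty rendered dataset", call. = FALSE)
  }
  model$params <- init_desknet_params(model$arch, hp$seed)
  adam <- list(
    m = lapply(model$params, function(w) w * 0),
    v = lapply(model$params, function(w) w * 0),
    t = 0
  )
  n <- nrow(train_set$x)
  log <- vector("list", hp$epochs)
  for (e in seq_len(hp$epochs)) {
    lr <- lr_schedule(hp, e)
    step <- with_seed(hp$seed * 1000L + e, {
      ord <- sample.int(n) - 1L
      draws <- if (hp$dropout_rate > 0) {
        matrix(stats::runif(n * model$arch$channels[4]), n)
      } else {
        matrix(numeric(0), 0, 0)
      }
      dn_train_epoch(
        model$params, adam, model$arch, train_set$x,
        as.integer(train_set$y), ord,
        train_set$height, train_set$width,
        lr, hp$weight_decay, hp$batch_size, hp$dropout_rate, draws
      )
    })
    model$params <- step$params
    adam <- step$adam
    val <- if (!is.null(val_set)) {
      eval_loss_acc(model, val_set)
    } else {
      list(loss = NA_real_, accuracy = NA_real_)
    }
    log[[e]] <- tibble::tibble(
      epoch = e, lr = lr,
      train_loss = step$loss, train_accuracy = step$accuracy,
      val_loss = val$loss, val_accuracy = val$accuracy
    )
    if (!quiet) {
      message(sprintf(
        "epoch %d/%d lr=%.5f train loss %.4f acc %.3f val acc %.3f",
        e, hp$epochs, lr, step$loss, step$accuracy, val$accuracy
      ))
    }
  }
  model$trained <- TRUE
  model$hp <- hp
  model$log <- dplyr::bind_rows(log)
  model
}

eval_loss_acc <- function(model, dataset) {
  logits <- dn_forward_batch(
    model$params, model$arch, dataset$x, dataset$height, dataset$width
  )
  pr <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(ifelse(dataset$y == 1, pr[, 2], pr[, 1]), eps)))
  acc <- mean((pr[, 2] > pr[, 1]) == (dataset$y == 1))
  list(loss = loss, accuracy = acc)
}

softmax_rows <- function(z) {
  m <- pmax(z[, 1], z[, 2])
  e1 <- exp(z[, 1] - m)
  e2 <- exp(z[, 2] - m)
  cbind(e1, e2) / (e1 + e2)
}

#' Predict classes for a rendered dataset
#'
#' @param object A (typically trained) `desknet` model.
#' @param dataset A `grating_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per image: `image_id`, logits, `prob_C2`
#'   and the predicted class.
#' @export
predict.desknet <- function(object, dataset, ...) {
  logits <- dn_forward_batch(
    object$params, object$arch, dataset$x, dataset$height, dataset$width
  )
  pr <- softmax_rows(logits)
  tibble::tibble(
    image_id = dataset$manifest$image_id,
    logit_C1 = logits[, 1], logit_C2 = logits[, 2],
    prob_C2 = pr[, 2],
    pred_class = factor(ifelse(pr[, 2] > pr[, 1], "C2", "C1"),
      levels = c("C1", "C2")
    )
  )
}

#' Evaluate a classifier: accuracy, recall, F1 and breakdowns
#'
#' C2 ("With-illusion" / tilted) is the positive class for recall and F1.
#' Per-hue and per-level accuracies are computed from the manifest metadata.
#'
#' @param model A trained `desknet` model.
#' @param dataset A non-empty `grating_dataset`.
#' @return A `metrics_report`: accuracy, recall, f1, precision, a 2x2
#'   confusion matrix (rows = truth, columns = prediction) and per-colour /
#'   per-level accuracy tibbles.
#' @export
evaluate <- function(model, dataset) {
  if (!inherits(dataset, "grating_dataset") || nrow(dataset$x) == 0) {
    stop("`dataset` must be a non-empty rendered dataset", call. = FALSE)
  }
  pred <- predict(model, dataset)
  truth <- factor(ifelse(dataset$y == 1, "C2", "C1"), levels = c("C1", "C2"))
  confusion <- table(truth = truth, pred = pred$pred_class)
  tp <- confusion["C2", "C2"]
  fn <- confusion["C2", "C1"]
  fp <- confusion["C1", "C2"]
  accuracy <- sum(diag(confusion)) / sum(confusion)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  by <- tibble::tibble(
    color_name = dataset$manifest$color_name,
    level = dataset$manifest$level,
    correct = truth == pred$pred_class
  )
  per_color <- dplyr::summarise(
    dplyr::group_by(by, .data$color_name),
    accuracy = mean(.data$correct), n = dplyr::n(), .groups = "drop"
  )
  per_level <- dplyr::summarise(
    dplyr::group_by(by, .data$level),
    accuracy = mean(.data$correct), n = dplyr::n(), .groups = "drop"
  )
  structure(
    list(
      accuracy = accuracy, recall = recall, precision = precision, f1 = f1,
      confusion = unclass(confusion),
      per_color_accuracy = per_color,
      per_level_accuracy = per_level,
      n = sum(confusion),
      predictions = pred
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d | accuracy %.4f | recall %.4f | F1 %.4f\n",
    x$n, x$accuracy, x$recall, x$f1
  ))
  print(x$confusion)
  invisible(x)
}

#' Nearest-rank percentile of a sample
#'
#' The `p`-th percentile is the value at ascending rank
#' `ceiling(p/100 * n)`.
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 100).
#' @return A single number.
#' @export
nearest_rank <- function(x, p) {
  stopifnot(length(x) >= 1, p > 0, p < 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

#' Permutation test of classifier significance
#'
#' Builds an empirical null for test accuracy by repeatedly shuffling the
#' training (and validation) class labels, retraining from the same
#' initialization policy, and evaluating on the unshuffled test set. The
#' observed accuracy is significant when it exceeds the nearest-rank
#' percentile (default 95th) of the null. Permutation `i` derives all its
#' randomness from `hp$seed + i`.
#'
#' @param model A `desknet` model (used as the architecture template). If
#'   untrained, the observed model is trained here with `hp` first.
#' @param train_set,val_set,test_set Rendered `grating_dataset`s; the test
#'   set keeps its true labels.
#' @param hp [hyperparams()] for every (re-)training run.
#' @param n_perms Number of permutations (the full protocol uses 1000;
#'   desk-scale runs use 20).
#' @param percentile Null percentile used as the significance baseline.
#' @param max_perms Guard against accidentally launching a full-scale run;
#'   raise it (or set `force = TRUE`) for more permutations.
#' @param force Bypass the `max_perms` guard.
#' @return A `permutation_result`: `null_accuracies`, `percentile95`,
#'   `actual_accuracy`, `significant`.
#' @export
permutation_test <- function(model, train_set, val_set = NULL, test_set,
                             hp = hyperparams(), n_perms = 20L,
                             percentile = 95, max_perms = 100L,
                             force = FALSE) {
  stopifnot(n_perms >= 1, percentile > 0, percentile < 100)
  if (n_perms > max_perms && !force) {
    stop(
      "n_perms = ", n_perms, " exceeds the configured budget (", max_perms,
      "); pass force = TRUE for a full-scale run",
      call. = FALSE
    )
  }
  if (!isTRUE(model$trained)) {
    model <- train(model, train_set, val_set, hp)
  }
  actual <- evaluate(model, test_set)$accuracy
  null_acc <- vapply(seq_len(n_perms), function(i) {
    seed_i <- hp$seed + i
    tr <- train_set
    tr$y <- with_seed(seed_i, sample(tr$y))
    vl <- val_set
    if (!is.null(vl)) vl$y <- with_seed(seed_i + 500000L, sample(vl$y))
    hp_i <- hp
    hp_i$seed <- seed_i
    m_i <- train(make_model(model$arch_name, channels = model$arch$channels),
      tr, vl, hp_i
    )
    evaluate(m_i, test_set)$accuracy
  }, numeric(1))
  baseline <- nearest_rank(null_acc, percentile)
  structure(
    list(
      null_accuracies = null_acc,
      percentile = percentile,
      percentile95 = baseline,
      actual_accuracy = actual,
      significant = actual > baseline,
      n_perms = n_perms
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d permutations | null %dth pct %.4f | actual %.4f | %s\n",
    x$n_perms, round(x$percentile), x$percentile95, x$actual_accuracy,
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}
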