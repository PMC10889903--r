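#' Configuration for an end-to-end run
#'
#' Defaults are desk-scale: small enough to finish on one CPU core in a few
#' minutes while exercising every stage. The full-scale protocol corresponds
#' to `per_level = 3000`, `independent_n = 1200`, `epochs = 100`,
#' `n_perms = 1000` at `downscale = 1`.
#'
#' @param per_level Training-pool images per illusion-strength level.
#' @param independent_n Size of the independent tilted test set.
#' @param downscale Integer block-averaging factor applied to every rendered
#'   image before the network sees it.
#' @param ratio Train:validation split ratio, length 2.
#' @param epochs,initial_lr,lr_decay_factor,lr_decay_every,weight_decay,dropout_rate,batch_size
#'   Training hyperparameters, see [hyperparams()].
#' @param n_perms Number of label permutations for the significance test.
#' @param percentile Null percentile used as the significance baseline.
#' @param rdm_mode Distance mode for representational analysis.
#' @param layers Tap names analysed by Grad-CAM and the RDM stack; `NULL`
#'   means all taps.
#' @param scene Rendered scene variant, `"full"` or `"plain"`.
#' @param seed Global seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(per_level = 50L, independent_n = 200L, downscale = 2L,
                       ratio = c(3, 1), epochs = 3L, initial_lr = 0.001,
                       lr_decay_factor = 0.9, lr_decay_every = 5L,
                       weight_decay = 1e-4, dropout_rate = 0,
                       batch_size = 32L, n_perms = 10L, percentile = 95,
                       rdm_mode = c("euclidean", "sq_sum"), layers = NULL,
                       scene = c("full", "plain"), seed = 1L) {
  rdm_mode <- match.arg(rdm_mode)
  scene <- match.arg(scene)
  stopifnot(
    per_level >= 1, independent_n >= 2, independent_n %% 2 == 0,
    downscale >= 1, length(ratio) == 2, n_perms >= 0
  )
  structure(
    list(
      per_level = as.integer(per_level),
      independent_n = as.integer(independent_n),
      downscale = as.integer(downscale),
      ratio = as.numeric(ratio),
      epochs = as.integer(epochs), initial_lr = initial_lr,
      lr_decay_factor = lr_decay_factor,
      lr_decay_every = as.integer(lr_decay_every),
      weight_decay = weight_decay, dropout_rate = dropout_rate,
      batch_size = as.integer(batch_size),
      n_perms = as.integer(n_perms), percentile = percentile,
      rdm_mode = rdm_mode, layers = layers,
      scene = scene, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys error; omitted keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat(
    "<run_config> per_level=", x$per_level,
    " independent_n=", x$independent_n,
    " downscale=", x$downscale,
    " epochs=", x$epochs,
    " n_perms=", x$n_perms,
    " seed=", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Run the full pipeline: stimuli to report
#'
#' Chains every stage: stimulus-grid enumeration, synthetic adjustment data,
#' dataset construction and rendering, training, evaluation on the
#' independent tilted set and the illusion set, the permutation significance
#' test, Grad-CAM on one exemplar per class, the cross-set RDM stack with
#' depth profile, and the combined framework score. A machine-readable
#' report is written as JSON, with the key tables alongside as CSV. A
#' failure in any stage aborts the run with the stage name in the error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with the fitted `model`, `metrics` (tilted and
#'   illusion), `perm`, `rdms`, `depth`, `score` and the report path.
#' @export
run_all <- function(config = run_config(), out_dir = "results",
                    quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf(
      "[%s] done in %.1fs", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ))
    out
  }

  grid <- stage("stimuli", enumerate_stimulus_grid())
  canvas <- attr(grid, "canvas")

  strengths <- stage("synthetic_human", {
    params <- response_model_params(seed = config$seed)
    aggregate_strengths(simulate_responses(grid, params))
  })

  datasets <- stage("datasets", {
    pool <- build_training_pool(
      per_level = config$per_level, grid = grid,
      seed = config$seed, scene = config$scene
    )
    splits <- split_train_val(pool, ratio = config$ratio, seed = config$seed)
    test_man <- build_independent_test(
      n = config$independent_n, grid = grid,
      seed = config$seed + 1L, scene = config$scene
    )
    ill_man <- build_illusion_test(strengths, grid)
    list(
      train = render_manifest(splits$train, canvas, config$downscale),
      # tiny pools can leave a level-stratified validation part empty
      val = if (nrow(splits$val) > 0) {
        render_manifest(splits$val, canvas, config$downscale)
      },
      test = render_manifest(test_man, canvas, config$downscale),
      illusion = render_manifest(ill_man, canvas, config$downscale)
    )
  })

  hp <- hyperparams(
    initial_lr = config$initial_lr,
    lr_decay_factor = config$lr_decay_factor,
    lr_decay_every = config$lr_decay_every,
    epochs = config$epochs, weight_decay = config$weight_decay,
    dropout_rate = config$dropout_rate, batch_size = config$batch_size,
    seed = config$seed
  )
  model <- stage("training", {
    train(make_model(seed = config$seed), datasets$train, datasets$val, hp,
      quiet = quiet
    )
  })

  metrics <- stage("evaluation", {
    list(
      tilted = evaluate(model, datasets$test),
      illusion = evaluate(model, datasets$illusion)
    )
  })

  perm <- if (config$n_perms > 0) {
    stage("permutation_test", {
      permutation_test(model, datasets$train, datasets$val, datasets$test,
        hp = hp, n_perms = config$n_perms, percentile = config$percentile
      )
    })
  } else {
    NULL
  }

  layers <- config$layers %||% model$taps
  cams <- stage("gradcam", {
    ill_pred <- metrics$illusion$predictions
    truth <- datasets$illusion$y
    pick <- function(cls) {
      ix <- which(truth == (cls == "C2"))[1]
      if (is.na(ix)) stop("no ", cls, " illusion image available")
      img <- render_manifest_row(datasets$illusion$manifest[ix, ], canvas)
      gradcam(model, img,
        class = cls, layer = layers[length(layers)],
        downscale = config$downscale
      )
    }
    list(C1 = pick("C1"), C2 = pick("C2"))
  })

  rdms <- stage("rdm", {
    cross_rdm_stack(model, strengths, grid,
      layers = layers,
      mode = config$rdm_mode, downscale = config$downscale
    )
  })
  depth <- stage("depth_profile", {
    depth_profile(model, strengths, grid,
      layers = layers,
      mode = config$rdm_mode, downscale = config$downscale
    )
  })
  score <- stage("framework_score", framework_score(cams, rdms))

  report_path <- stage("report", {
    report <- list(
      config = unclass(config),
      training = list(log = model$log),
      metrics = list(
        tilted = glance(metrics$tilted),
        illusion = glance(metrics$illusion),
        per_level_tilted = metrics$tilted$per_level_accuracy
      ),
      permutation = if (!is.null(perm)) glance(perm) else NULL,
      rdm = lapply(rdms, glance),
      depth_profile = depth,
      framework_score = list(
        score = score$score,
        rdm_summary = score$rdm_summary,
        gradcam_summary = score$gradcam_summary,
        layer_id = score$layer_id
      )
    )
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, path,
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    readr::write_csv(strengths, file.path(out_dir, "strengths.csv"))
    readr::write_csv(
      metrics$tilted$predictions,
      file.path(out_dir, "predictions_tilted.csv")
    )
    readr::write_csv(
      dplyr::bind_rows(lapply(rdms, tidy), .id = "layer_id"),
      file.path(out_dir, "rdm.csv")
    )
    path
  })

  say(sprintf(
    "run complete: tilted accuracy %.3f, illusion accuracy %.3f%s",
    metrics$tilted$accuracy, metrics$illusion$accuracy,
    if (!is.null(perm)) {
      sprintf(
        ", permutation %s",
        if (perm$significant) "significant" else "not significant"
      )
    } else {
      ""
    }
  ))
  invisible(list(
    model = model, metrics = metrics, perm = perm,
    rdms = rdms, depth = depth, score = score,
    strengths = strengths, report = report_path
  ))
}
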