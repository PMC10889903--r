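test_that("hyperparameters validate and the LR schedule steps correctly", {
  hp <- hyperparams()
  expect_equal(hp$initial_lr, 0.001)
  expect_equal(lr_schedule(hp, 1:4), rep(0.001, 4))
  expect_equal(lr_schedule(hp, 5:9), rep(0.0009, 5))
  expect_equal(lr_schedule(hp, 10), 0.00081)
  expect_error(hyperparams(initial_lr = 0))
  expect_error(hyperparams(dropout_rate = 1))
  expect_error(hyperparams(optimizer = "sgd"))
})

test_that("the model registry validates its arguments", {
  expect_error(make_model("resnet101"), "unknown architecture")
  expect_error(make_model(pretrained = TRUE), "pretrained")
  m <- make_model()
  expect_s3_class(m, "desknet")
  expect_false(m$trained)
  expect_equal(m$taps, c("conv1", "conv2", "conv3", "conv4"))
  # parameter shapes: 3x3 kernels over (3 RGB + 2 coordinate) channels
  expect_equal(dim(m$params$W1), c(12, 5 * 9))
  expect_equal(dim(m$params$W2), c(16, 12 * 9))
  expect_equal(dim(m$params$Wd), c(2, 16))
  expect_length(m$params$b3, 16)
})

test_that("weight initialization is seed-deterministic", {
  expect_identical(make_model(seed = 7L)$params, make_model(seed = 7L)$params)
  expect_false(identical(
    make_model(seed = 7L)$params$W1, make_model(seed = 8L)$params$W1
  ))
})

test_that("training is reproducible and learns a separable toy problem", {
  grid <- small_grid()
  pool <- build_training_pool(per_level = 6L, grid = grid, seed = 1L)
  sp <- split_train_val(pool, seed = 1L)
  tr <- render_small(sp$train)
  vl <- render_small(sp$val)
  hp <- hyperparams(epochs = 3L, seed = 1L)
  m1 <- train(make_model(), tr, vl, hp)
  m2 <- train(make_model(), tr, vl, hp)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
  expect_true(m1$trained)
  expect_equal(nrow(m1$log), 3)
  expect_named(
    m1$log,
    c("epoch", "lr", "train_loss", "train_accuracy", "val_loss", "val_accuracy")
  )
  # loss should come down from its ~log(2) start on this tiny problem
  expect_lt(m1$log$train_loss[3], m1$log$train_loss[1])
  expect_error(train(make_model(), list()), "rendered dataset")
})

test_that("prediction and evaluation agree with a manual confusion oracle", {
  grid <- small_grid()
  pool <- build_training_pool(per_level = 4L, grid = grid, seed = 2L)
  ds <- render_small(pool)
  m <- train(make_model(), ds, hp = hyperparams(epochs = 1L))
  pred <- predict(m, ds)
  expect_equal(nrow(pred), nrow(pool))
  expect_equal(pred$pred_class, factor(
    ifelse(pred$prob_C2 > 0.5, "C2", "C1"),
    levels = c("C1", "C2")
  ))
  rep <- evaluate(m, ds)
  truth <- ifelse(ds$y == 1, "C2", "C1")
  guess <- as.character(pred$pred_class)
  expect_equal(rep$accuracy, mean(truth == guess))
  tp <- sum(truth == "C2" & guess == "C2")
  fn <- sum(truth == "C2" & guess == "C1")
  fp <- sum(truth == "C1" & guess == "C2")
  expect_equal(rep$recall, tp / (tp + fn))
  expect_equal(rep$precision, tp / (tp + fp))
  expect_equal(rep$f1, 2 * rep$precision * rep$recall /
    (rep$precision + rep$recall))
  expect_equal(sum(rep$confusion), nrow(pool))
  expect_equal(sum(rep$per_level_accuracy$n), nrow(pool))
})

test_that("nearest-rank percentile matches the type-1 quantile oracle", {
  set.seed(8)
  for (i in 1:5) {
    x <- runif(sample(5:40, 1))
    for (p in c(5, 50, 95)) {
      expect_equal(
        nearest_rank(x, p),
        unname(stats::quantile(x, p / 100, type = 1))
      )
    }
  }
  expect_equal(nearest_rank(c(3, 1, 2), 95), 3)
  expect_equal(nearest_rank(1:100, 95), 95)
  expect_error(nearest_rank(1:3, 100))
})

test_that("the permutation test guards against full-scale budgets", {
  grid <- small_grid()
  ds <- render_small(build_training_pool(per_level = 2L, grid = grid, seed = 3L))
  expect_error(
    permutation_test(make_model(), ds, NULL, ds, n_perms = 101L),
    "budget"
  )
  res <- permutation_test(make_model(), ds, NULL, ds,
    hp = hyperparams(epochs = 1L), n_perms = 2L
  )
  expect_s3_class(res, "permutation_result")
  expect_length(res$null_accuracies, 2)
  expect_equal(res$percentile95, nearest_rank(res$null_accuracies, 95))
  expect_equal(res$significant, res$actual_accuracy > res$percentile95)
})
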