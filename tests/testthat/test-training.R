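test_that("the 7:3 split is disjoint, exhaustive and deterministic", {
  idx <- split_dataset(10, 0.7, seed = 5)
  expect_length(idx$train, 7)
  expect_length(idx$validation, 3)
  expect_setequal(c(idx$train, idx$validation), 1:10)
  expect_identical(idx, split_dataset(10, 0.7, seed = 5))
  expect_false(identical(idx, split_dataset(10, 0.7, seed = 6)))
  expect_error(split_dataset(1, 0.7, 1), "at least 2")
})

test_that("the split reproduces the modelling-set bookkeeping at n = 38112", {
  idx <- split_dataset(38112, 0.7, seed = 1)
  expect_length(idx$train, 26678)
  expect_length(idx$validation, 11434)
})

test_that("splitting a dataset carries images and labels together", {
  cfg <- tiny_scene(seed = 2)
  data <- preprocess_dataset(generate_dataset(10, cfg), 64)
  sp <- split_dataset(data, 0.7, seed = 9)
  expect_equal(dim(sp$train$images)[3], 7)
  expect_equal(nrow(sp$validation$labels), 3)
  idx <- split_dataset(10, 0.7, seed = 9)
  expect_equal(sp$train$labels, data$labels[idx$train, ])
  expect_equal(sp$train$images[, , 4], data$images[, , idx$train[4]])
})

test_that("total_loss matches the stated worked examples", {
  y <- matrix(runif(6 * 4, 10, 100), 4, 6)
  expect_equal(total_loss(y, y), 0)
  expect_equal(total_loss(rep(1, 6), rep(2, 6)), 6)  # every target off by 1
  # per-target errors {(1,3),(0,2),(2,2),(1,1),(0,0),(3,1)} -> MSEs 5,2,4,1,0,5
  err <- rbind(c(1, 0, 2, 1, 0, 3), c(3, 2, 2, 1, 0, 1))
  meas <- matrix(50, 2, 6)
  expect_equal(total_loss(meas + err, meas), 17)
  expect_error(total_loss(matrix(0, 2, 6), matrix(0, 3, 6)), "M x 6")
})

test_that("total_loss equals the brute-force double sum on random batches", {
  set.seed(44)
  for (i in 1:100) {
    m <- sample(1:20, 1)
    y <- matrix(runif(m * 6, 1, 150), m, 6)
    yhat <- y + matrix(rnorm(m * 6, 0, 5), m, 6)
    a <- total_loss(yhat, y)
    b <- naive_total_loss(yhat, y)
    expect_lt(abs(a - b) / max(b, 1e-12), 1e-10)
  }
})

test_that("total_loss is invariant to simultaneous sample permutation", {
  set.seed(45)
  y <- matrix(runif(60, 1, 100), 10, 6)
  yhat <- y + rnorm(60)
  p <- sample(10)
  expect_equal(total_loss(yhat, y), total_loss(yhat[p, ], y[p, ]))
})

test_that("training records history and retains the best checkpoint", {
  cfg <- tiny_scene(size = 64, seed = 6)
  data <- preprocess_dataset(generate_dataset(40, cfg), 64)
  m <- build_regressor(model_spec("tinycnn", input_size = 64))

  fit1 <- train(m, data, train_config(epochs = 1, shuffle_seed = 11))
  expect_equal(nrow(fit1$history), 1)
  expect_equal(fit1$best_epoch, 1)

  fit <- train(m, data, train_config(epochs = 5, shuffle_seed = 11))
  expect_equal(fit$best_val_loss, min(fit$history$val_loss))
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # re-evaluating the retained parameters reproduces the stored loss
  sp <- split_dataset(data, 0.7, seed = 11)
  pred <- predict(fit$model, sp$validation$images)
  re_loss <- total_loss(pred, sp$validation$labels)
  expect_lt(abs(re_loss - fit$best_val_loss) / fit$best_val_loss, 1e-6)
})

test_that("seeded training runs are reproducible", {
  cfg <- tiny_scene(size = 64, seed = 7)
  data <- preprocess_dataset(generate_dataset(20, cfg), 32)
  m <- build_regressor(model_spec("tinycnn", input_size = 32))
  f1 <- train(m, data, train_config(epochs = 2, shuffle_seed = 21))
  f2 <- train(m, data, train_config(epochs = 2, shuffle_seed = 21))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$head_w, f2$model$head_w)
})

test_that("branched backbones are rejected by the trainer with guidance", {
  data <- structure(list(images = array(0L, c(224, 224, 2)),
                         labels = matrix(1, 2, 6)), class = "regression_dataset")
  expect_error(train(build_regressor("mobilenetv2"), data), "tinycnn")
})
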