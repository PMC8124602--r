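# A hand-computed parameter tally for the tinycnn backbone: four 3x3
# convolutions with bias (3->16->32->64->256 channels) plus six (F+1)-sized
# heads on the 256-wide pooled features.
tinycnn_expected_params <- function() {
  convs <- sum(3 * 3 * c(3 * 16, 16 * 32, 32 * 64, 64 * 256) + c(16, 32, 64, 256))
  convs + 6 * (256 + 1)
}

test_that("tinycnn parameter count equals the layer-wise arithmetic oracle", {
  m <- build_regressor("tinycnn")
  pc <- count_parameters(m)
  expect_identical(pc$total, tinycnn_expected_params())
  expect_identical(pc$trainable, pc$total)  # no batch norm in tinycnn
})

test_that("the six heads contribute exactly 6 * (F + 1) parameters", {
  for (b in c("tinycnn", "mobilenetv2")) {
    m <- build_regressor(b)
    backbone_only <- sum(pigdepth:::graph_param_table(m$graph)$n)
    pc <- count_parameters(m)
    expect_identical(pc$total - backbone_only, 6 * (m$feature_width + 1))
  }
  # the 2048-wide pooled backbone: 6 * 2049 = 12,294 head parameters
  mx <- build_regressor("xception")
  expect_identical(6 * (mx$feature_width + 1), 12294)
})

test_that("unknown backbones are rejected with the valid names", {
  expect_error(build_regressor("vgg16"), "densenet201")
  expect_error(model_spec("nope"), "tinycnn")
})

test_that("input sizes are pinned for the named backbones", {
  expect_error(model_spec("xception", input_size = 224), "299")
  expect_error(model_spec("densenet201", input_size = 299), "224")
  expect_silent(model_spec("tinycnn", input_size = 96))
})

test_that("zero-initialised heads give exactly zero output", {
  m <- init_model_weights(build_regressor("tinycnn"), seed = 1, head_init = "zero")
  out <- predict(m, matrix(0L, 64, 64))
  expect_identical(dim(out), c(1L, 6L))
  expect_identical(colnames(out), c("BW", "SW", "SH", "HW", "HH", "BL"))
  expect_true(all(out == 0))
})

test_that("a branched backbone produces six finite scalars per image", {
  m <- init_model_weights(build_regressor("mobilenetv2"), seed = 2)
  out <- predict(m, matrix(128L, 224, 224))
  expect_identical(dim(out), c(1L, 6L))
  expect_true(all(is.finite(out)))
})

test_that("predict rejects uninitialised models and wrong image sizes", {
  m <- build_regressor("tinycnn")
  expect_error(predict(m, matrix(0L, 64, 64)), "init_model_weights")
  m <- init_model_weights(m, 1)
  expect_error(predict(m, matrix(0L, 32, 32)), "64")
})

test_that("head i is trained against label i (overfit one sample)", {
  set.seed(33)
  img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
  target <- c(3, 1, 4, 2, 5, 9)
  data <- structure(list(images = array(rep(img, 10), c(32, 32, 10)),
                         labels = matrix(target, 10, 6, byrow = TRUE,
                                         dimnames = list(NULL, c("BW", "SW", "SH", "HW", "HH", "BL")))),
                    class = "regression_dataset")
  m <- build_regressor(model_spec("tinycnn", input_size = 32))
  fit <- train(m, data, train_config(epochs = 200, batch_size = 16, shuffle_seed = 3))
  pred <- predict(fit$model, img)
  expect_lt(max(abs(pred - target)), 0.2)
  # training loss collapses to < 1e-3 of its initial value
  expect_lt(tail(fit$history$train_loss, 1), 1e-3 * fit$history$train_loss[1])
})
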