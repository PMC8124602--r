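test_that("metrics match the stated worked examples", {
  y <- c(10, 20, 30)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(y, y), 0)
  expect_equal(mre(y, y), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)

  # errors (3, -4): rmse = sqrt(25/2), mae = 3.5
  expect_equal(rmse(c(10, 10), c(13, 6)), sqrt(25 / 2))
  expect_equal(mae(c(10, 10), c(13, 6)), 3.5)
  # constant shift c: both equal |c|
  expect_equal(rmse(y, y + 2.5), 2.5)
  expect_equal(mae(y, y - 2.5), 2.5)

  expect_equal(mre(100, 98), 2)
  expect_equal(mre(c(50, 100), c(55, 90)), 10)

  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)  # predicting the mean
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
})

test_that("metric edge cases raise informative errors", {
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(mae(1:3, 1:2), "length")
  expect_error(mre(c(0, 1), c(1, 1)), "non-zero")
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("metrics agree with brute-force loops on random instances", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    y <- runif(n, 5, 150)
    yhat <- y + rnorm(n, 0, 4)
    expect_lt(abs(rmse(y, yhat) - naive_rmse(y, yhat)) / naive_rmse(y, yhat), 1e-10)
    expect_lt(abs(mae(y, yhat) - naive_mae(y, yhat)) / naive_mae(y, yhat), 1e-10)
    expect_lt(abs(mre(y, yhat) - naive_mre(y, yhat)) / naive_mre(y, yhat), 1e-10)
    expect_lt(abs(r_squared(y, yhat) - naive_r_squared(y, yhat)) /
                max(abs(naive_r_squared(y, yhat)), 1e-12), 1e-10)
  }
})

test_that("rmse dominates mae and both are order-invariant", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    y <- runif(n, 10, 100)
    yhat <- y + rnorm(n, 0, 3)
    expect_gte(rmse(y, yhat), mae(y, yhat))
    p <- sample(n)
    expect_equal(rmse(y, yhat), rmse(y[p], yhat[p]))
    expect_equal(mae(y, yhat), mae(y[p], yhat[p]))
    expect_equal(mre(y, yhat), mre(y[p], yhat[p]))
    expect_equal(r_squared(y, yhat), r_squared(y[p], yhat[p]))
  }
  # equality holds iff all absolute errors are equal
  y <- c(10, 20, 30)
  expect_equal(rmse(y, y + c(2, -2, 2)), mae(y, y + c(2, -2, 2)))
})

test_that("evaluate assembles a coherent report", {
  cfg <- tiny_scene(seed = 8)
  data <- preprocess_dataset(generate_dataset(12, cfg), 64)
  m <- init_model_weights(build_regressor(model_spec("tinycnn", input_size = 64)), 1)
  rep <- evaluate(m, data)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n, 12)
  expect_identical(rep$per_target$target, c("BW", "SW", "SH", "HW", "HH", "BL"))
  expect_equal(rep$total_mse, sum(rep$per_target$rmse^2))
  expect_true(all(rep$per_target$rmse >= rep$per_target$mae))
  expect_gt(rep$mean_estimation_time_ms, 0)
})
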