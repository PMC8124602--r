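test_that("the capture rule applies range and strict-spread checks", {
  cfg <- trigger_config()
  expect_true(should_capture(c(50.0, 50.1, 50.05, 49.95), cfg))   # spread 0.15
  expect_false(should_capture(c(50.0, 50.1, 50.3, 49.95), cfg))   # spread 0.35
  expect_false(should_capture(c(50.0, 50.2, 50.1, 50.1), cfg))    # spread exactly 0.2
  expect_false(should_capture(c(10, 10, 10, 10), cfg))            # below population range
  expect_true(should_capture(c(16.5, 16.5, 16.5, 16.5), cfg))     # closed interval
  expect_true(should_capture(c(117, 117, 117, 117), cfg))
  expect_error(should_capture(c(50, 50, 50), cfg), "exactly 4")
})

test_that("stream scanning handles plateaus, cooldowns and edge cases", {
  cfg <- trigger_config()
  # a stable 10-reading plateau fires at windows ending at 4 and 8
  ev <- process_stream(rep(60, 10), cfg)
  expect_equal(ev$index, c(4, 8))
  expect_equal(process_stream(rep(5, 20), cfg)$index, integer())   # out of range
  expect_equal(nrow(process_stream(numeric(), cfg)), 0)            # empty stream
  # refractory 0: every qualifying window fires
  cfg0 <- trigger_config(refractory_readings = 0)
  expect_equal(process_stream(rep(60, 10), cfg0)$index, 4:10)
  # unordered timestamps are rejected
  bad <- data.frame(timestamp_ms = c(2, 1, 3, 4), weight_kg = rep(60, 4))
  expect_error(process_stream(bad, cfg), "non-decreasing")
})

test_that("event timestamps come from the triggering reading, in ms", {
  r <- data.frame(timestamp_ms = seq(1000, by = 200, length.out = 8),
                  weight_kg = c(80, 80.05, 80.1, 80.02, 5, 5, 5, 5))
  ev <- process_stream(r, trigger_config())
  expect_equal(ev$index, 4)
  expect_equal(ev$timestamp_ms, 1600)
  expect_equal(ev$weight_kg, mean(c(80, 80.05, 80.1, 80.02)))
})

test_that("process_stream matches the brute-force window scan", {
  set.seed(66)
  for (trial in 1:200) {
    n <- sample(4:60, 1)
    # weights hover around the range edges and the spread boundary
    w <- round(runif(n, 10, 125) + rnorm(n, 0, 0.1), 3)
    refractory <- sample(0:6, 1)
    cfg <- trigger_config(refractory_readings = refractory)
    got <- process_stream(w, cfg)$index
    want <- brute_force_events(w, refractory = refractory)
    expect_equal(got, as.integer(want), ignore_attr = TRUE)
  }
})

test_that("enlarging the spread tolerance never removes an event", {
  set.seed(67)
  for (trial in 1:50) {
    w <- 60 + cumsum(rnorm(40, 0, 0.12))
    e1 <- process_stream(w, trigger_config(max_spread_kg = 0.2, refractory_readings = 0))$index
    e2 <- process_stream(w, trigger_config(max_spread_kg = 0.5, refractory_readings = 0))$index
    expect_true(all(e1 %in% e2))
  }
})
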