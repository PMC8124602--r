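test_that("depth inversion is the stated involution with exact endpoints", {
  img <- matrix(c(0, 825, 1650, 1000), 2, 2)
  h <- invert_depth(img, 1650)
  expect_equal(h, matrix(c(1650, 825, 0, 650), 2, 2), ignore_attr = TRUE)
  expect_equal(invert_depth(h, 1650), img, ignore_attr = TRUE)   # involution
  # pixels above the camera clip to zero height with a warning count
  expect_warning(h2 <- invert_depth(matrix(c(1700, 100), 1), 1650), "1 pixel")
  expect_equal(as.numeric(h2), c(0, 1550))
  expect_equal(attr(h2, "n_clipped"), 1)
})

test_that("gray scaling maps endpoints exactly and rounds half up", {
  expect_equal(scale_to_gray(matrix(0), 1650)[1, 1], 0L)
  expect_equal(scale_to_gray(matrix(1650), 1650)[1, 1], 255L)
  # 825 / 1650 * 255 = 127.5, round half up
  expect_equal(scale_to_gray(matrix(825), 1650)[1, 1], 128L)
  expect_error(scale_to_gray(matrix(c(1, NaN), 1), 1650), "\\(1, 2\\)")
  expect_error(scale_to_gray(matrix(2000), 1650), "camera_distance_mm")
})

test_that("height to gray is monotone, end to end", {
  set.seed(21)
  h <- sort(runif(500, 0, 1650))
  g <- scale_to_gray(matrix(h, 1), 1650)
  expect_true(all(diff(as.integer(g)) >= 0))
  # raising a surface point (smaller depth) never darkens it
  d <- sort(runif(500, 0, 1650), decreasing = TRUE)
  g2 <- scale_to_gray(invert_depth(matrix(d, 1), 1650), 1650)
  expect_true(all(diff(as.integer(g2)) >= 0))
})

test_that("bilinear resize matches the brute-force resampler", {
  set.seed(22)
  for (dims in list(c(12, 20, 7), c(9, 9, 5), c(30, 14, 17))) {
    x <- matrix(runif(dims[1] * dims[2], 0, 255), dims[1], dims[2])
    mine <- pigdepth:::`.resize_bilinear`(x, dims[3], dims[3])
    expect_equal(mine, naive_resize(x, dims[3], dims[3]), tolerance = 1e-12)
  }
})

test_that("resize keeps constants, is idempotent and mean-preserving", {
  const <- matrix(77L, 45, 80)
  out <- resize_gray(const, 24)
  expect_true(all(out == 77L))
  expect_equal(dim(out), c(24L, 24L))
  once <- resize_gray(matrix(sample(0:255, 64 * 64, TRUE), 64), 32)
  expect_identical(resize_gray(once, 32), once)
  expect_error(resize_gray(const, 4), "at least 8")
  # full-frame checkerboard of period 2: the mean survives downsampling
  cb <- matrix(rep_len(c(0L, 255L), 1280 * 720), 720, 1280)
  out <- resize_gray(cb, 224)
  expect_lt(abs(mean(out) - mean(cb)), 1)
})

test_that("preprocessing preserves the pig's relative position", {
  cfg <- scene_config(depth_noise_std_mm = 0)
  ph <- pig_phenotype(90, 24, 54, 22, 50, 50, yaw_deg = 5, lateral_offset_cm = 6)
  img <- render_depth(ph, cfg, noise = FALSE)
  height <- 1650 - as.numeric(img)
  rows <- matrix(seq_len(720), 720, 1280)
  cols <- matrix(seq_len(1280), 720, 1280, byrow = TRUE)
  cen_before <- c(sum(rows * height), sum(cols * height)) / sum(height)

  gray <- preprocess_depth(img, 224)
  g <- as.numeric(gray)
  rows2 <- matrix(seq_len(224), 224, 224)
  cols2 <- matrix(seq_len(224), 224, 224, byrow = TRUE)
  cen_after <- c(sum(rows2 * g), sum(cols2 * g)) / sum(g)

  rescaled <- cen_before * c(224 / 720, 224 / 1280)
  expect_lt(max(abs(cen_after - rescaled)), 1)
})

test_that("the full chain is deterministic", {
  cfg <- tiny_scene(seed = 30)
  img <- generate_dataset(1, cfg)$images[[1]]
  expect_identical(preprocess_depth(img, 64), preprocess_depth(img, 64))
})
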