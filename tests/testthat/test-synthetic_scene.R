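test_that("phenotype sampling is seed-deterministic", {
  p1 <- sample_phenotype(c(16.5, 117), seed = 7)
  p2 <- sample_phenotype(c(16.5, 117), seed = 7)
  expect_identical(p1, p2)
  p3 <- sample_phenotype(c(16.5, 117), seed = 8)
  expect_false(identical(p1, p3))
})

test_that("traits scale linearly and weight cubically in the latent size", {
  p1 <- phenotype_from_latent(0.8)
  p2 <- phenotype_from_latent(1.6)
  for (f in c("body_length_cm", "shoulder_width_cm", "shoulder_height_cm",
              "hip_width_cm", "hip_height_cm"))
    expect_equal(p2[[f]], 2 * p1[[f]])
  expect_equal(p2$body_weight_kg, 8 * p1$body_weight_kg)
})

test_that("sampled weights stay in range with the configured mean", {
  set.seed(101)
  rng <- c(16.5, 117)
  bw <- replicate(1000, sample_phenotype(rng)$body_weight_kg)
  expect_true(all(bw >= rng[1] & bw <= rng[2]))
  # BW is uniform over the range by construction: mean (min+max)/2,
  # se = width / sqrt(12 n)
  se <- diff(rng) / sqrt(12 * length(bw))
  expect_lt(abs(mean(bw) - mean(rng)), 3 * se)
})

test_that("phenotype validation names the offending field", {
  expect_error(sample_phenotype(c(10, 5)), "weight_range_kg")
  expect_error(sample_phenotype(c(16.5, 117), density_g_cm3 = NaN), "density_g_cm3")
  expect_error(pig_phenotype(-1, 26, 56, 24, 54, 60), "body_length_cm")
  expect_error(pig_phenotype(100, 26, 56, 24, NA, 60), "hip_height_cm")
})

test_that("apex of the rendered back is max(SH, HH) below the camera", {
  cfg <- scene_config(depth_noise_std_mm = 0)
  ph <- pig_phenotype(100, 26, 60, 24, 55, 60, head_pitch_cm = 0)
  img <- render_depth(ph, cfg, noise = FALSE)
  expect_lte(abs(min(img) - (1650 - 600)), 1)  # quantisation step
  # hip taller than shoulder: apex follows HH
  ph2 <- pig_phenotype(100, 26, 55, 24, 62, 60, head_pitch_cm = 0)
  img2 <- render_depth(ph2, cfg, noise = FALSE)
  expect_lte(abs(min(img2) - (1650 - 620)), 1)
})

test_that("empty scene is exactly the camera distance everywhere", {
  cfg <- tiny_scene(depth_noise_std_mm = 0)
  img <- render_depth(NULL, cfg, noise = FALSE)
  expect_true(all(img == cfg$camera_distance_mm))
})

test_that("raising SH never raises the minimum pixel value", {
  cfg <- scene_config(depth_noise_std_mm = 0)
  mins <- vapply(seq(50, 64, by = 2), function(sh) {
    ph <- pig_phenotype(100, 26, sh, 24, 52, 60, head_pitch_cm = 0)
    min(render_depth(ph, cfg, noise = FALSE))
  }, 0)
  expect_true(all(diff(mins) <= 0))
})

test_that("rendered height integral matches the analytic loft volume", {
  cfg <- scene_config(depth_noise_std_mm = 0)
  set.seed(11)
  for (i in 1:10) {
    ph <- sample_phenotype(c(16.5, 117))
    img <- render_depth(ph, cfg, noise = FALSE)
    v_img <- rendered_volume_cm3(img, cfg)
    v_ana <- body_volume_cm3(ph, as_imaged = TRUE)
    expect_lt(abs(v_img - v_ana) / v_ana, 0.02)
    # the closed-form volume itself agrees with fine numeric integration
    expect_equal(v_ana, numeric_volume_cm3(ph, as_imaged = TRUE), tolerance = 1e-6)
  }
  # 4x the default resolution tightens the discretisation error to 0.5%
  cfg4 <- scene_config(image_height_px = 2880, image_width_px = 5120,
                       depth_noise_std_mm = 0)
  ph <- sample_phenotype(c(16.5, 117), seed = 5)
  v_img <- rendered_volume_cm3(render_depth(ph, cfg4, noise = FALSE), cfg4)
  expect_lt(abs(v_img - body_volume_cm3(ph, as_imaged = TRUE)) /
              body_volume_cm3(ph, as_imaged = TRUE), 0.005)
})

test_that("weight tracks rendered volume when weight noise is off", {
  cfg <- scene_config(image_height_px = 180, image_width_px = 320,
                      depth_noise_std_mm = 0, weight_noise_sd = 0)
  ds <- generate_dataset(200, cfg, seed = 3)
  vols <- vapply(ds$images, rendered_volume_cm3, 0, config = cfg)
  expect_gt(cor(ds$labels[, "BW"], vols), 0.99)
})

test_that("generate_dataset is reproducible and respects invariants", {
  cfg <- tiny_scene(seed = 9)
  d1 <- generate_dataset(5, cfg)
  d2 <- generate_dataset(5, cfg)
  expect_identical(d1$labels, d2$labels)
  for (i in 1:5) expect_identical(unclass(d1$images[[i]]), unclass(d2$images[[i]]))

  d3 <- generate_dataset(100, tiny_scene(), seed = 4)
  expect_true(all(d3$labels > 0))
  expect_true(all(d3$labels[, "BW"] >= 16.5 & d3$labels[, "BW"] <= 117))
  expect_true(all(vapply(d3$images, function(im) all(im >= 0 & im <= 1650), TRUE)))
  expect_error(generate_dataset(0, cfg), "n must be")
})

test_that("SH label semantics follow the configured head-pitch convention", {
  cfg_img <- tiny_scene(sh_label = "as_imaged", seed = 12)
  cfg_rest <- tiny_scene(sh_label = "at_rest", seed = 12)
  d_img <- generate_dataset(10, cfg_img)
  d_rest <- generate_dataset(10, cfg_rest)
  pitch <- vapply(d_img$phenotypes, function(p) p$head_pitch_cm, 0)
  expect_equal(d_img$labels[, "SH"] - d_rest$labels[, "SH"], pitch)
  # all other labels unchanged
  expect_equal(d_img$labels[, -3], d_rest$labels[, -3])
})

test_that("phenotypes that overhang the platform are rejected by name", {
  cfg <- tiny_scene()
  big <- pig_phenotype(140, 30, 60, 28, 58, 110)   # 168 cm with appendages
  expect_error(render_depth(big, cfg, noise = FALSE), "platform_length_m")
  wide <- pig_phenotype(100, 30, 60, 28, 58, 80, lateral_offset_cm = 18)
  expect_error(render_depth(wide, cfg, noise = FALSE), "platform_width_m")
})

test_that("limit bars render as raised rails without touching the pig", {
  cfg <- tiny_scene(include_limit_bars = TRUE, depth_noise_std_mm = 0)
  img <- render_depth(NULL, cfg, noise = FALSE)
  expect_true(any(img == 1650 - 700))
  expect_true(all(img %in% c(1650L, 950L)))
})
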