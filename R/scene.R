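# Depth-scene simulator.
#
# Renders a pig phenotype as seen by a depth camera mounted 1650 mm above a
# 1.5 m x 0.5 m weighing platform: each pixel holds the camera-to-surface
# distance in integer millimetres, background pixels the camera-to-platform
# distance.  The geometry is the lofted half-elliptical solid of
# phenotype.R, so every rendered image has analytically known labels and an
# analytically known enclosed volume.

#' Scene and acquisition configuration
#'
#' @param camera_distance_mm camera height above the platform (mm).
#' @param image_height_px,image_width_px depth image size (rows, cols).
#' @param platform_length_m,platform_width_m platform extent; the image x
#'   axis (columns) runs along the platform length.
#' @param mm_per_pixel ground sampling distance; default spreads the
#'   platform length across the image width.
#' @param depth_noise_std_mm sd of the Gaussian sensor noise added to each
#'   pixel (then clipped to `[0, camera_distance_mm]` and quantised to mm).
#' @param include_limit_bars render the two side limit bars of the crate as
#'   raised rails along the platform edges.
#' @param weight_range_kg population body-weight range.
#' @param density_g_cm3,weight_noise_sd,shape_noise_sd population parameters
#'   passed to [sample_phenotype()].
#' @param sh_label label semantics for SH, see [phenotype_labels()].
#' @param seed default RNG seed for [generate_dataset()].
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(camera_distance_mm = 1650,
                         image_height_px = 720, image_width_px = 1280,
                         platform_length_m = 1.5, platform_width_m = 0.5,
                         mm_per_pixel = NULL, depth_noise_std_mm = 2,
                         include_limit_bars = FALSE,
                         weight_range_kg = c(16.5, 117),
                         density_g_cm3 = 1, weight_noise_sd = 0.03,
                         shape_noise_sd = 0.02,
                         sh_label = c("as_imaged", "at_rest"), seed = NULL) {
  sh_label <- match.arg(sh_label)
  if (image_height_px < 64 || image_width_px < 64)
    stop("image dimensions must be at least 64 pixels")
  if (is.null(mm_per_pixel)) mm_per_pixel <- platform_length_m * 1000 / image_width_px
  cfg <- list(camera_distance_mm = camera_distance_mm,
              image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              platform_length_m = platform_length_m,
              platform_width_m = platform_width_m,
              mm_per_pixel = mm_per_pixel,
              depth_noise_std_mm = depth_noise_std_mm,
              include_limit_bars = include_limit_bars,
              weight_range_kg = weight_range_kg,
              density_g_cm3 = density_g_cm3,
              weight_noise_sd = weight_noise_sd,
              shape_noise_sd = shape_noise_sd,
              sh_label = sh_label, seed = seed)
  # tallest achievable back: largest pig, +5% shape noise, +4 cm head pitch
  unit <- phenotype_from_latent(1, density_g_cm3 = density_g_cm3)
  size_max <- (weight_range_kg[2] * exp(3 * weight_noise_sd) /
                 unit$body_weight_kg)^(1 / 3)
  max_height_cm <- PIG_BASE[["SH"]] * size_max * 1.05 + 4
  if (camera_distance_mm <= cm_to_mm(max_height_cm))
    stop("camera_distance_mm (", camera_distance_mm,
         ") must exceed the maximum achievable body height (",
         round(cm_to_mm(max_height_cm)), " mm)")
  class(cfg) <- "scene_config"
  cfg
}

# Lateral spine displacement (cm) of a bent pig at axial position s (cm
# from the snout-to-tail midpoint); parabolic arc, max sag bend * L / 8.
bend_offset_cm <- function(s_rel_cm, bend_deg, total_len_cm) {
  (bend_deg * pi / 180) / (2 * total_len_cm) * s_rel_cm^2
}

check_platform_fit <- function(phen, config) {
  pr <- PIG_PROFILE
  total_len <- phen$body_length_cm * (1 + pr$head_frac + pr$tail_frac)
  half_w <- phen$shoulder_width_cm / 2 +
    abs(bend_offset_cm(total_len / 2, phen$bend_deg, total_len))
  th <- phen$yaw_deg * pi / 180
  len_extent <- total_len / 2 * abs(cos(th)) + half_w * abs(sin(th))
  wid_extent <- total_len / 2 * abs(sin(th)) + half_w * abs(cos(th)) +
    abs(phen$lateral_offset_cm)
  if (len_extent > config$platform_length_m * 100 / 2)
    stop("phenotype exceeds platform_length_m: body extent ",
         round(2 * len_extent), " cm > ", config$platform_length_m * 100, " cm")
  if (wid_extent > config$platform_width_m * 100 / 2)
    stop("phenotype exceeds platform_width_m: body extent ",
         round(2 * wid_extent), " cm > ", config$platform_width_m * 100, " cm")
  invisible(TRUE)
}

#' Render a phenotype to a depth image
#'
#' @param phen a [pig_phenotype()], or `NULL` for an empty scene.
#' @param config a [scene_config()].
#' @param noise add Gaussian sensor noise (sd `config$depth_noise_std_mm`)
#'   from the current RNG stream.
#' @param timestamp_ms acquisition timestamp (ms) stored on the image.
#' @return an integer matrix of class `depth_image`
#'   (`image_height_px x image_width_px`, camera distance in mm) with
#'   attributes `camera_distance_mm` and `timestamp_ms`.
#' @export
render_depth <- function(phen, config = scene_config(), noise = TRUE,
                         timestamp_ms = 0) {
  h_px <- config$image_height_px
  w_px <- config$image_width_px
  mpp <- config$mm_per_pixel
  cam <- config$camera_distance_mm
  height <- matrix(0, h_px, w_px)  # surface height above platform, mm

  if (!is.null(phen)) {
    stopifnot(inherits(phen, "pig_phenotype"))
    check_platform_fit(phen, config)
    # pixel-centre world coordinates (mm), origin at the platform centre;
    # x along the platform length (columns), y across it (rows)
    x <- (seq_len(w_px) - 0.5) * mpp - w_px * mpp / 2
    y <- (seq_len(h_px) - 0.5) * mpp - h_px * mpp / 2
    X <- matrix(x, h_px, w_px, byrow = TRUE)
    Y <- matrix(y, h_px, w_px)

    th <- phen$yaw_deg * pi / 180
    dy <- Y - cm_to_mm(phen$lateral_offset_cm)
    sb <- cos(th) * X + sin(th) * dy   # axial, mm, 0 at body midpoint
    tb <- -sin(th) * X + cos(th) * dy  # lateral, mm

    prof <- body_profile(phen, as_imaged = TRUE)
    s_mm <- cm_to_mm(prof$s)
    mid <- (s_mm[1] + s_mm[length(s_mm)]) / 2
    s_body <- sb + mid  # profile coordinate: 0 at the ear root
    total_len_cm <- prof$s[length(prof$s)] - prof$s[1]
    t_body <- tb - cm_to_mm(bend_offset_cm(mm_to_cm(sb), phen$bend_deg, total_len_cm))

    w_s <- approx(s_mm, cm_to_mm(prof$w), s_body, yleft = 0, yright = 0)$y
    a_s <- approx(s_mm, cm_to_mm(prof$a), s_body, yleft = 0, yright = 0)$y
    inside <- w_s > 0 & abs(as.numeric(t_body)) < w_s
    hh <- numeric(length(w_s))
    hh[inside] <- a_s[inside] * sqrt(1 - (as.numeric(t_body)[inside] / w_s[inside])^2)
    height <- matrix(hh, h_px, w_px)
  }

  if (isTRUE(config$include_limit_bars)) {
    y <- (seq_len(h_px) - 0.5) * mpp - h_px * mpp / 2
    bar_rows <- abs(abs(y) - config$platform_width_m * 1000 / 2) <= 15
    height[bar_rows, ] <- pmax(height[bar_rows, ], 700)
  }

  depth <- cam - height
  if (noise && config$depth_noise_std_mm > 0)
    depth <- depth + rnorm(length(depth), 0, config$depth_noise_std_mm)
  depth <- pmin(pmax(depth, 0), cam)
  img <- matrix(as.integer(round(depth)), h_px, w_px)
  structure(img, camera_distance_mm = cam, timestamp_ms = timestamp_ms,
            class = c("depth_image", class(img)))
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n` independent phenotypes from the configured population, renders
#' each to a depth image and attaches the six labels in the order BW, SW,
#' SH, HW, HH, BL.
#'
#' @param n number of scenes (>= 1).
#' @param config a [scene_config()].
#' @param seed integer RNG seed (falls back to `config$seed`, then 1).
#' @return a list of class `pig_scene_dataset` with elements `images` (list
#'   of `depth_image`), `labels` (`n x 6` matrix), `phenotypes`,
#'   `timestamps_ms` and `config`.
#' @export
generate_dataset <- function(n, config = scene_config(), seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  set.seed(as.integer(seed))

  images <- vector("list", n)
  phenotypes <- vector("list", n)
  labels <- matrix(0, n, 6, dimnames = list(NULL, TARGET_NAMES))
  # millisecond acquisition timestamps with irregular gaps
  ts <- 1.7e12 + cumsum(round(runif(n, 2e3, 6e4)))
  for (i in seq_len(n)) {
    phen <- sample_phenotype(config$weight_range_kg, seed = NULL,
                             density_g_cm3 = config$density_g_cm3,
                             weight_noise_sd = config$weight_noise_sd,
                             shape_noise_sd = config$shape_noise_sd,
                             platform_length_m = config$platform_length_m,
                             platform_width_m = config$platform_width_m)
    images[[i]] <- render_depth(phen, config, noise = config$depth_noise_std_mm > 0,
                                timestamp_ms = ts[i])
    phenotypes[[i]] <- phen
    labels[i, ] <- phenotype_labels(phen, sh_label = config$sh_label)
  }
  structure(list(images = images, labels = labels, phenotypes = phenotypes,
                 timestamps_ms = ts, config = config),
            class = "pig_scene_dataset")
}

#' @export
print.pig_scene_dataset <- function(x, ...) {
  cat(sprintf("<pig_scene_dataset> %d scenes, %dx%d px, BW %.1f-%.1f kg\n",
              length(x$images), x$config$image_height_px, x$config$image_width_px,
              min(x$labels[, "BW"]), max(x$labels[, "BW"])))
  invisible(x)
}
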