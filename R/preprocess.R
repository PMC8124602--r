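# Depth-to-gray preprocessing.
#
# The raw depth image stores the camera-to-surface distance P_o; the model
# input is built by (i) inverting each pixel, P_i = camera_distance - P_o,
# so the value becomes height above the platform, (ii) scaling 0..camera
# distance linearly to 0..255 (round half up), and (iii) resizing to a
# square model input with bilinear resampling.  The chain changes neither
# the relative position nor the relative size of the pig in the frame.

#' Invert a depth image to a height field
#'
#' @param image depth matrix (mm from the camera).
#' @param camera_distance_mm camera height; defaults to the image attribute.
#' @return numeric matrix of surface heights above the platform (mm).  An
#'   attribute `n_clipped` counts pixels that were above the camera
#'   (negative height) and were clipped to 0; a warning reports the count.
#' @export
invert_depth <- function(image, camera_distance_mm = attr(image, "camera_distance_mm")) {
  if (is.null(camera_distance_mm))
    stop("camera_distance_mm is required (none stored on the image)")
  height <- camera_distance_mm - unclass(image)
  n_clipped <- sum(height < 0)
  if (n_clipped > 0) {
    warning(n_clipped, " pixel(s) above the camera were clipped to height 0")
    height[height < 0] <- 0
  }
  height <- matrix(as.numeric(height), nrow(image), ncol(image))
  attr(height, "n_clipped") <- n_clipped
  height
}

#' Scale a height field to 8-bit gray
#'
#' Linear map of `[0, camera_distance_mm]` to `[0, 255]` with round half
#' up, so 0 maps to 0, the full camera distance maps to 255, and lighter
#' always means higher.
#'
#' @param height numeric matrix of heights in mm.
#' @param camera_distance_mm full-scale height.
#' @return integer matrix of class `gray_image` with values in 0..255.
#' @export
scale_to_gray <- function(height, camera_distance_mm = 1650) {
  if (any(!is.finite(height))) {
    bad <- which(!is.finite(height), arr.ind = TRUE)
    stop("non-finite height at (row, col): ",
         paste(sprintf("(%d, %d)", bad[, 1], bad[, 2])[seq_len(min(5, nrow(bad)))],
               collapse = ", "))
  }
  if (any(height < 0) || any(height > camera_distance_mm))
    stop("heights must lie in [0, camera_distance_mm]")
  g <- floor(unclass(height) / camera_distance_mm * 255 + 0.5)
  g <- matrix(as.integer(g), nrow(height), ncol(height))
  structure(g, class = c("gray_image", class(g)))
}

#' Resize a gray image
#'
#' Bilinear resampling to a square target; the aspect ratio is not
#' preserved (a 1280 x 720 frame is squashed to the square model input, no
#' padding), so relative positions within the frame are unchanged.
#'
#' @param image gray matrix (0..255).
#' @param target_size output side length; the standard model inputs are 299
#'   and 224, and any size >= 8 is accepted for desk-scale backbones.
#' @return integer `gray_image` of size `target_size x target_size`.
#' @export
resize_gray <- function(image, target_size = 224L) {
  if (target_size < 8) stop("target_size must be at least 8")
  target_size <- as.integer(target_size)
  out <- .resize_bilinear(matrix(as.numeric(image), nrow(image), ncol(image)),
                          target_size, target_size)
  out <- floor(pmin(pmax(out, 0), 255) + 0.5)
  structure(matrix(as.integer(out), target_size, target_size),
            class = c("gray_image", "matrix", "array"))
}

#' Full preprocessing chain
#'
#' Inversion, 0-255 scaling and square resize, in that order.
#'
#' @param image a `depth_image` (or depth matrix in mm).
#' @param target_size model input side length.
#' @param camera_distance_mm camera height; defaults to the image attribute,
#'   then to 1650 mm.
#' @return integer `gray_image` of size `target_size x target_size`.
#' @export
preprocess_depth <- function(image, target_size = 224L,
                             camera_distance_mm = attr(image, "camera_distance_mm")) {
  if (is.null(camera_distance_mm)) camera_distance_mm <- 1650
  height <- invert_depth(image, camera_distance_mm)
  gray <- scale_to_gray(height, camera_distance_mm)
  resize_gray(gray, target_size)
}

#' Preprocess a whole dataset
#'
#' @param dataset a `pig_scene_dataset` from [generate_dataset()].
#' @param target_size model input side length.
#' @return a list of class `regression_dataset` with `images` (an
#'   `(S, S, n)` array of gray values) and `labels` (`n x 6`).
#' @export
preprocess_dataset <- function(dataset, target_size = 224L) {
  stopifnot(inherits(dataset, "pig_scene_dataset"))
  n <- length(dataset$images)
  x <- array(0L, c(target_size, target_size, n))
  for (i in seq_len(n)) x[, , i] <- preprocess_depth(dataset$images[[i]], target_size)
  structure(list(images = x, labels = dataset$labels), class = "regression_dataset")
}
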