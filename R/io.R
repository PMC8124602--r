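# File formats: 16-bit depth PNGs, 8-bit gray PNGs, CSV label manifests.
#
# Depth PNGs store the camera distance in millimetres directly as 16-bit
# grayscale samples (no scaling), so the height inversion applies verbatim
# to stored values.  Image file names are millisecond acquisition
# timestamps.

#' Write a depth image as 16-bit grayscale PNG
#'
#' @param image integer depth matrix (mm), values 0..65535.
#' @param path output file.
#' @export
write_depth_png <- function(image, path) {
  m <- matrix(as.integer(unclass(image)), nrow(image), ncol(image))
  .png_write_gray(path, m, 16L)
  invisible(path)
}

#' Read a 16-bit grayscale depth PNG
#'
#' @param path PNG file; must be single-channel 16-bit grayscale.
#' @param camera_distance_mm camera height recorded on the returned image.
#' @return an integer matrix of class `depth_image` (mm).
#' @export
read_depth_png <- function(path, camera_distance_mm = 1650) {
  res <- .png_read_gray(path)
  if (res$bit_depth != 16)
    stop("expected a 16-bit grayscale depth PNG, got bit depth ", res$bit_depth,
         " in '", path, "'")
  ts <- suppressWarnings(as.numeric(sub("\\.png$", "", basename(path))))
  structure(res$image, camera_distance_mm = camera_distance_mm,
            timestamp_ms = if (is.finite(ts)) ts else NA_real_,
            class = c("depth_image", class(res$image)))
}

#' Write a gray image as 8-bit grayscale PNG
#' @param image integer gray matrix, values 0..255.
#' @param path output file.
#' @export
write_gray_png <- function(image, path) {
  m <- matrix(as.integer(unclass(image)), nrow(image), ncol(image))
  .png_write_gray(path, m, 8L)
  invisible(path)
}

#' Read an 8-bit grayscale PNG
#' @param path PNG file; must be single-channel 8-bit grayscale.
#' @return an integer matrix of class `gray_image`.
#' @export
read_gray_png <- function(path) {
  res <- .png_read_gray(path)
  if (res$bit_depth != 8)
    stop("expected an 8-bit grayscale PNG, got bit depth ", res$bit_depth,
         " in '", path, "'")
  structure(res$image, class = c("gray_image", class(res$image)))
}

manifest_header <- function() c("image", TARGET_NAMES)

#' Write a dataset manifest
#'
#' One row per image: the image file name (a millisecond timestamp) and the
#' six labels in the fixed order BW, SW, SH, HW, HH, BL.
#'
#' @param filenames character vector of image file names.
#' @param labels `n x 6` label matrix.
#' @param path output CSV.
#' @export
write_manifest <- function(filenames, labels, path) {
  stopifnot(length(filenames) == nrow(labels), ncol(labels) == 6)
  df <- data.frame(image = filenames, labels, stringsAsFactors = FALSE)
  names(df) <- manifest_header()
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' @param path manifest CSV.
#' @param check_files verify that every referenced image exists next to the
#'   manifest.
#' @return a data frame with columns `image`, `BW`, `SW`, `SH`, `HW`, `HH`,
#'   `BL`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), manifest_header()))
    stop("manifest header must be exactly: ", paste(manifest_header(), collapse = ","))
  lab <- as.matrix(df[, TARGET_NAMES])
  if (any(!is.finite(lab)) || any(lab <= 0))
    stop("manifest labels must be six finite positive numbers per row (row ",
         which(rowSums(!is.finite(lab) | lab <= 0) > 0)[1], " is not)")
  if (check_files) {
    paths <- file.path(dirname(path), df$image)
    missing <- df$image[!file.exists(paths)]
    if (length(missing))
      stop("manifest references missing image(s): ",
           paste(head(missing, 3), collapse = ", "))
  }
  df
}

#' Save a scene dataset to disk
#'
#' Writes each depth image as `<timestamp_ms>.png` (16-bit) plus a
#' `manifest.csv` in `dir`.
#'
#' @param dataset a `pig_scene_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_scene_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pig_scene_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fns <- sprintf("%013.0f.png", dataset$timestamps_ms)
  for (i in seq_along(dataset$images))
    write_depth_png(dataset$images[[i]], file.path(dir, fns[i]))
  write_manifest(fns, dataset$labels, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a depth dataset from a manifest directory
#'
#' @param dir directory holding `manifest.csv` and the referenced 16-bit
#'   depth PNGs.
#' @param camera_distance_mm camera height for the loaded images.
#' @return a `pig_scene_dataset` (without phenotypes).
#' @export
load_scene_dataset <- function(dir, camera_distance_mm = 1650) {
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  images <- lapply(file.path(dir, mf$image), read_depth_png,
                   camera_distance_mm = camera_distance_mm)
  structure(list(images = images,
                 labels = as.matrix(mf[, TARGET_NAMES]),
                 phenotypes = NULL,
                 timestamps_ms = as.numeric(sub("\\.png$", "", mf$image)),
                 config = NULL),
            class = "pig_scene_dataset")
}

# CRC-32 of a configuration list (canonical JSON), for artifact provenance.
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  crc <- .crc32_bytes(charToRaw(as.character(json)))
  sprintf("%04x%04x", crc %/% 65536, crc %% 65536)
}
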