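# Reading and writing 8-bit RGB images (PNG, TIFF, JPEG).

#' Read an RGB image file
#'
#' Supports PNG, TIFF and JPEG (by extension). Images are decoded as
#' sRGB-encoded 8-bit data; an alpha channel, if present, is dropped and
#' grayscale images are expanded to three identical channels. No ICC profile
#' handling is attempted.
#'
#' @param path image file path.
#' @return an [rgb_image()] with values on `[0, 255]`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format '.%s' (use png/tiff/jpeg)", ext),
         call. = FALSE)
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  rgb_image(raw * 255, source_path = path)
}

#' Write an RGB image file
#'
#' @param image an [rgb_image()] (or H x W x 3 array on `[0, 255]`).
#' @param path output path; format chosen by extension (png/tiff/jpeg).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    jpg = ,
    jpeg = jpeg::writeJPEG(arr, path, quality = 0.98),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}
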