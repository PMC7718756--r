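# sRGB <-> CIELAB conversion constants (D65 white, 2 degree observer).
# Matrix rows map linear RGB -> XYZ.
.srgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)
.xyz2srgb <- solve(.srgb2xyz)
.d65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.lab_eps <- (6 / 29)^3
.lab_kap <- (29 / 6)^2 / 3   # slope of the linear segment of f()

.as_rgb_matrix <- function(rgb) {
  if (is.null(dim(rgb))) {
    if (length(rgb) %% 3L != 0L)
      stop("rgb values must be length-3 or an n x 3 matrix", call. = FALSE)
    rgb <- matrix(rgb, ncol = 3, byrow = length(rgb) == 3L)
  }
  if (ncol(rgb) != 3L) stop("rgb must have 3 columns", call. = FALSE)
  storage.mode(rgb) <- "double"
  rgb
}

#' Convert sRGB values to CIELAB
#'
#' Standard sRGB decoding (gamma expansion), linear RGB to XYZ under the D65
#' white point (2 degree observer), then XYZ to CIE L*a*b*. This is the
#' reference conversion behind calibration fitting and the synthetic tray
#' renderer.
#'
#' @param rgb a length-3 vector or an n x 3 matrix of channel values in
#'   `[0, 255]` (R, G, B order).
#' @return an n x 3 matrix with columns `L`, `a`, `b`; `L` in `[0, 100]`.
#' @examples
#' srgb_to_lab(c(255, 255, 255))  # reference white: (100, 0, 0)
#' srgb_to_lab(c(118, 118, 118))  # mid gray, L about 49.6
#' @seealso [lab_to_srgb()], [delta_e()]
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- .as_rgb_matrix(rgb)
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255))
    stop("rgb channel values must lie in [0, 255]", call. = FALSE)
  s <- rgb / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(.srgb2xyz)
  xyz <- sweep(xyz, 2, .d65, "/")
  f <- ifelse(xyz > .lab_eps, xyz^(1 / 3), .lab_kap * xyz + 4 / 29)
  out <- cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
  out
}

#' Convert CIELAB values to sRGB
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colors are clipped to the sRGB
#' cube and flagged through the `"clipped"` attribute; for in-gamut colors
#' the round trip is accurate to well under 0.5 dE.
#'
#' @param lab a length-3 vector or an n x 3 matrix (`L`, `a`, `b`).
#' @return an n x 3 matrix of sRGB channel values in `[0, 255]` with a
#'   logical `"clipped"` attribute (one entry per row).
#' @export
lab_to_srgb <- function(lab) {
  lab <- .as_rgb_matrix(lab)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f^3 > .lab_eps, f^3, (f - 4 / 29) / .lab_kap)
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  xyz <- sweep(xyz, 2, .d65, "*")
  lin <- xyz %*% t(.xyz2srgb)
  clipped <- apply(lin < -1e-9 | lin > 1 + 1e-9, 1, any)
  lin <- pmin(pmax(lin, 0), 1)
  s <- ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
  out <- s * 255
  colnames(out) <- c("R", "G", "B")
  attr(out, "clipped") <- clipped
  out
}

#' CIE76 color difference
#'
#' Euclidean distance in CIELAB space, the error metric used throughout for
#' calibration accuracy and kernel/background contrast.
#'
#' @param x,y length-3 Lab vectors or n x 3 matrices (recycled row-wise).
#' @return a numeric vector of non-negative distances.
#' @export
delta_e <- function(x, y) {
  x <- .as_rgb_matrix(x)
  y <- .as_rgb_matrix(y)
  if (nrow(x) != nrow(y)) {
    if (nrow(x) == 1L) x <- x[rep(1L, nrow(y)), , drop = FALSE]
    else if (nrow(y) == 1L) y <- y[rep(1L, nrow(x)), , drop = FALSE]
    else stop("x and y must have the same number of rows", call. = FALSE)
  }
  sqrt(rowSums((x - y)^2))
}

#' Construct an RGB image object
#'
#' A light wrapper around an H x W x 3 numeric array with channel values on
#' the 8-bit `[0, 255]` scale.
#'
#' @param pixels an H x W x 3 array in `[0, 255]`.
#' @param source_path optional provenance string.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0 | pixels > 255))
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, class = "rgb_image", color_depth = 8L,
            source_path = source_path)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels (8-bit)\n", d[1], d[2]))
  invisible(x)
}

.pixel_matrix <- function(img) {
  d <- dim(img)
  matrix(as.numeric(img), nrow = d[1] * d[2], ncol = 3L)
}

#' White-balance correction from a reference image
#'
#' Corrects illumination using an image of a uniform white reference taken
#' under the same lighting. The default `"flatfield"` method divides each
#' pixel by the (lightly smoothed) local white-balance value and rescales to
#' the 8-bit maximum, so a spatial illumination gradient recorded in the WB
#' image is removed. `"global"` applies a single per-channel gain
#' `255 / max(wb channel)`; `"subtract"` adds the offset `255 - max(wb
#' channel)` per channel. For a spatially uniform WB image the flat-field and
#' global methods coincide.
#'
#' @param image an [rgb_image()] to correct.
#' @param wb_image an [rgb_image()] of the white reference. For
#'   `"flatfield"` it must share dimensions with `image`.
#' @param method one of `"flatfield"`, `"global"`, `"subtract"`.
#' @param smooth_sigma Gaussian blur (pixels) applied to the WB image before
#'   flat-fielding, to suppress sensor noise; 0 disables.
#' @return the corrected [rgb_image()], clipped to `[0, 255]`.
#' @export
white_balance_correct <- function(image, wb_image,
                                  method = c("flatfield", "global", "subtract"),
                                  smooth_sigma = 3) {
  method <- match.arg(method)
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  if (!inherits(wb_image, "rgb_image")) wb_image <- rgb_image(wb_image)
  wmax <- apply(wb_image, 3, max)
  if (any(wmax <= 0))
    stop("degenerate calibration: a white-balance channel has zero maximum",
         call. = FALSE)
  out <- unclass(image)
  if (method == "global") {
    gains <- 255 / wmax
    for (k in 1:3) out[, , k] <- out[, , k] * gains[k]
  } else if (method == "subtract") {
    for (k in 1:3) out[, , k] <- out[, , k] + (255 - wmax[k])
  } else {
    if (!all(dim(image)[1:2] == dim(wb_image)[1:2]))
      stop("image and wb_image dimensions differ", call. = FALSE)
    wb <- unclass(wb_image)
    if (smooth_sigma > 0 && min(dim(wb)[1:2]) > 4) {
      for (k in 1:3)
        wb[, , k] <- as.matrix(EBImage::gblur(EBImage::Image(wb[, , k]),
                                              sigma = smooth_sigma))
    }
    if (any(wb <= 0))
      stop("degenerate calibration: white-balance image contains zero pixels",
           call. = FALSE)
    out <- out * (255 / wb)
  }
  out <- pmin(pmax(out, 0), 255)
  rgb_image(out, source_path = attr(image, "source_path"))
}
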