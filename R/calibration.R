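# Color-checker based RGB -> CIELAB calibration.

.poly_terms <- function(rgb01, degree) {
  r <- rgb01[, 1]; g <- rgb01[, 2]; b <- rgb01[, 3]
  if (degree == 1L) {
    cbind(`(Intercept)` = 1, R = r, G = g, B = b)
  } else {
    cbind(`(Intercept)` = 1, R = r, G = g, B = b,
          R2 = r^2, G2 = g^2, B2 = b^2, RG = r * g, RB = r * b, GB = g * b)
  }
}

#' Color-checker reference chart
#'
#' Describes the patches of a color checker: rectangular pixel regions in the
#' checker photograph and the known L*a*b* value of each patch.
#'
#' @param patch_ids character vector of patch labels.
#' @param patch_regions data frame or matrix with columns `x0, y0, x1, y1`
#'   (0-based, half-open pixel rectangles: rows `y0..y1-1`, cols `x0..x1-1`).
#' @param reference_labs n x 3 matrix of L*a*b* values, one row per patch.
#' @return an object of class `checker_reference`.
#' @export
checker_reference <- function(patch_ids, patch_regions, reference_labs) {
  patch_regions <- as.data.frame(patch_regions)
  names(patch_regions) <- c("x0", "y0", "x1", "y1")
  reference_labs <- .as_rgb_matrix(reference_labs)
  n <- length(patch_ids)
  if (n < 4L) stop("a checker needs at least 4 patches", call. = FALSE)
  if (nrow(patch_regions) != n || nrow(reference_labs) != n)
    stop("patch_ids, patch_regions and reference_labs lengths differ",
         call. = FALSE)
  if (any(patch_regions$x1 <= patch_regions$x0) ||
      any(patch_regions$y1 <= patch_regions$y0))
    stop("patch regions must have positive extent", call. = FALSE)
  colnames(reference_labs) <- c("L", "a", "b")
  structure(list(patch_ids = as.character(patch_ids),
                 patch_regions = patch_regions,
                 reference_labs = reference_labs),
            class = "checker_reference")
}

#' Read a color-checker reference from CSV
#'
#' Columns: `patch_id, x0, y0, x1, y1, L, a, b`. Lines starting with `#` are
#' treated as metadata comments.
#'
#' @param path CSV file path.
#' @return a [checker_reference()].
#' @export
read_checker_reference <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  checker_reference(df$patch_id, df[, c("x0", "y0", "x1", "y1")],
                    as.matrix(df[, c("L", "a", "b")]))
}

#' Mean patch RGB values from a checker photograph
#' @keywords internal
.patch_means <- function(image, reference) {
  img <- unclass(image)
  t(vapply(seq_len(nrow(reference$patch_regions)), function(i) {
    r <- reference$patch_regions[i, ]
    rows <- (r$y0 + 1):r$y1
    cols <- (r$x0 + 1):r$x1
    c(mean(img[rows, cols, 1]), mean(img[rows, cols, 2]),
      mean(img[rows, cols, 3]))
  }, numeric(3)))
}

#' Fit a polynomial RGB -> CIELAB calibration from a color checker
#'
#' Averages the pixels of each checker patch (optionally after white-balance
#' correction) and fits a least-squares polynomial map from patch RGB to the
#' reference L*a*b* values. Degree 1 uses the terms `{1, R, G, B}` (an affine
#' map); degree 2 adds squares and pairwise products (10 terms). The training
#' error is the mean CIE76 dE over patches.
#'
#' @param checker_image [rgb_image()] of the checker, already white-balanced
#'   if a WB reference is in use.
#' @param reference a [checker_reference()].
#' @param degree polynomial degree, 1 or 2.
#' @param wb_gains per-channel gains recorded in the model metadata
#'   (default 1, i.e. WB handled upstream).
#' @return an object of class `calibration_model` with elements
#'   `degree`, `wb_gains`, `coefficients` (terms x 3), `fit_error`.
#' @export
fit_calibration <- function(checker_image, reference, degree = 1L,
                            wb_gains = c(1, 1, 1)) {
  stopifnot(inherits(reference, "checker_reference"))
  degree <- as.integer(degree)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  if (any(wb_gains <= 0)) stop("wb_gains must be positive", call. = FALSE)
  rgb <- .patch_means(checker_image, reference)
  n_terms <- if (degree == 1L) 4L else 10L
  if (nrow(rgb) < n_terms)
    stop(sprintf("insufficient patches: %d patches for %d polynomial terms",
                 nrow(rgb), n_terms), call. = FALSE)
  X <- .poly_terms(rgb / 255, degree)
  qx <- qr(X)
  if (qx$rank < n_terms)
    stop("collinear patch colors: calibration design is rank deficient",
         call. = FALSE)
  coef <- qr.coef(qx, reference$reference_labs)
  fitted <- X %*% coef
  fit_error <- mean(delta_e(fitted, reference$reference_labs))
  structure(list(degree = degree, wb_gains = as.numeric(wb_gains),
                 coefficients = coef, fit_error = fit_error,
                 color_space = "CIELAB (D65, 2 deg observer)",
                 n_patches = nrow(rgb)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> degree %d (%d terms), %d patches\n",
              x$degree, nrow(x$coefficients), x$n_patches))
  cat(sprintf("  color space: %s\n  training mean dE: %.4g\n",
              x$color_space, x$fit_error))
  invisible(x)
}

#' Map calibration model over RGB values
#' @keywords internal
.calibrate_rgb <- function(rgb, model) {
  rgb <- sweep(rgb, 2, model$wb_gains, "*")
  rgb <- pmin(pmax(rgb, 0), 255)
  lab <- .poly_terms(rgb / 255, model$degree) %*% model$coefficients
  lab[, 1] <- pmin(pmax(lab[, 1], 0), 100)
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' Apply a fitted calibration to an image
#'
#' Maps every pixel through the model's white-balance gains and polynomial,
#' yielding a per-pixel L*a*b* image. L* is clipped to `[0, 100]`.
#'
#' @param image an [rgb_image()].
#' @param model a fitted [fit_calibration()] model.
#' @return a `calibrated_image`: H x W x 3 array of L*, a*, b* planes.
#' @export
apply_calibration <- function(image, model) {
  if (!inherits(model, "calibration_model"))
    stop("model must be a fitted calibration_model", call. = FALSE)
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  d <- dim(image)
  lab <- .calibrate_rgb(.pixel_matrix(image), model)
  out <- array(lab, dim = d)
  structure(out, class = "calibrated_image",
            color_space = model$color_space)
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<calibrated_image> %d x %d pixels, %s\n", d[1], d[2],
              attr(x, "color_space")))
  invisible(x)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path output (input) file path.
#' @return `read_calibration` returns the restored `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(degree = model$degree, wb_gains = model$wb_gains,
              terms = rownames(model$coefficients),
              coefficients = unname(model$coefficients),
              fit_error = model$fit_error, color_space = model$color_space,
              n_patches = model$n_patches)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- as.matrix(obj$coefficients)
  rownames(coef) <- obj$terms
  colnames(coef) <- c("L", "a", "b")
  structure(list(degree = as.integer(obj$degree), wb_gains = obj$wb_gains,
                 coefficients = coef, fit_error = obj$fit_error,
                 color_space = obj$color_space,
                 n_patches = as.integer(obj$n_patches)),
            class = "calibration_model")
}
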