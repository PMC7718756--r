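# Segmentation of kernels from 100-well scoring trays and per-kernel
# L*a*b* measurement.

#' Tray layout
#'
#' Geometry of a scoring tray: a grid of wells inside a bounding box. The
#' commercial trays hold 100 kernels in a 10 x 10 grid. The well grid is an
#' equal subdivision of `tray_bbox`; wells are indexed 0-based by
#' `(row, col)` from the top-left.
#'
#' @param rows,cols well grid dimensions.
#' @param tray_bbox pixel rectangle `c(x0, y0, x1, y1)` (0-based, half-open)
#'   enclosing the well grid.
#' @param background_lab optional known tray background L*a*b*; when `NULL`
#'   it is estimated from the calibrated image at segmentation time.
#' @return an object of class `tray_layout`.
#' @export
tray_layout <- function(rows = 10L, cols = 10L, tray_bbox,
                        background_lab = NULL) {
  stopifnot(rows >= 1, cols >= 1, length(tray_bbox) == 4)
  if (tray_bbox[3] <= tray_bbox[1] || tray_bbox[4] <= tray_bbox[2])
    stop("tray_bbox must have positive extent", call. = FALSE)
  if (!is.null(background_lab)) background_lab <- as.numeric(background_lab)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 tray_bbox = as.numeric(tray_bbox),
                 background_lab = background_lab),
            class = "tray_layout")
}

#' @export
print.tray_layout <- function(x, ...) {
  cat(sprintf("<tray_layout> %d x %d wells, bbox [%g,%g) x [%g,%g)\n",
              x$rows, x$cols, x$tray_bbox[1], x$tray_bbox[3],
              x$tray_bbox[2], x$tray_bbox[4]))
  invisible(x)
}

.cell_size <- function(layout) {
  c(w = (layout$tray_bbox[3] - layout$tray_bbox[1]) / layout$cols,
    h = (layout$tray_bbox[4] - layout$tray_bbox[2]) / layout$rows)
}

# Merge bwlabel (4-connectivity) components that touch diagonally, giving
# 8-connectivity labels. Union-find over the label adjacency graph.
.labels_8conn <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  m <- as.matrix(EBImage::imageData(lab))
  nlab <- max(m)
  if (nlab <= 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  pairs <- rbind(
    cbind(as.vector(m[-nr, -nc]), as.vector(m[-1, -1])),   # down-right
    cbind(as.vector(m[-1, -nc]), as.vector(m[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  m[m > 0] <- relab[m[m > 0]]
  m
}

#' Estimate the tray background color
#'
#' Channel-wise median L*a*b* over the tray bounding box of a calibrated
#' image. Kernels occupy a minority of the tray area, so the median is a
#' robust estimate of the tray material color.
#'
#' @param image a `calibrated_image`.
#' @param layout a [tray_layout()].
#' @return a length-3 L*a*b* vector.
#' @export
estimate_background_lab <- function(image, layout) {
  bb <- layout$tray_bbox
  rows <- (floor(bb[2]) + 1):ceiling(bb[4])
  cols <- (floor(bb[1]) + 1):ceiling(bb[3])
  img <- unclass(image)
  c(L = stats::median(img[rows, cols, 1]),
    a = stats::median(img[rows, cols, 2]),
    b = stats::median(img[rows, cols, 3]))
}

#' Segment kernels from the tray background
#'
#' A pixel is foreground when its CIE76 dE to the background color exceeds
#' `delta_e_threshold` — a chromatic criterion that captures both light and
#' dark kernels, unlike a single luminance cut. The mask is cleaned by a
#' 3 x 3 morphological opening, labelled into 8-connected components, and
#' components smaller than `min_area` pixels are discarded.
#'
#' @param image a `calibrated_image` (from [apply_calibration()]).
#' @param layout a [tray_layout()].
#' @param delta_e_threshold foreground threshold in dE units (default 12).
#' @param min_area minimum component area in pixels; default 0.5% of a well
#'   cell's area.
#' @param background_lab override for the background color; default
#'   `layout$background_lab`, estimated from the image if that is `NULL`.
#' @return a list with `components` (data frame: `id, area, centroid_x,
#'   centroid_y`), `labels` (H x W label matrix) and `background_lab`.
#' @export
segment_kernels <- function(image, layout, delta_e_threshold = 12,
                            min_area = NULL, background_lab = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (delta_e_threshold <= 0)
    stop("delta_e_threshold must be positive", call. = FALSE)
  if (is.null(background_lab)) background_lab <- layout$background_lab
  if (is.null(background_lab))
    background_lab <- estimate_background_lab(image, layout)
  if (is.null(min_area)) {
    cs <- .cell_size(layout)
    min_area <- max(1, floor(0.005 * cs["w"] * cs["h"]))
  }
  d <- dim(image)
  lab <- matrix(as.numeric(unclass(image)), nrow = d[1] * d[2], ncol = 3L)
  de <- delta_e(lab, background_lab)
  mask <- matrix(de > delta_e_threshold, nrow = d[1], ncol = d[2])
  # restrict to the tray bbox
  bb <- layout$tray_bbox
  keep <- matrix(FALSE, d[1], d[2])
  keep[(floor(bb[2]) + 1):ceiling(bb[4]), (floor(bb[1]) + 1):ceiling(bb[3])] <- TRUE
  mask <- mask & keep
  kern <- EBImage::makeBrush(3, shape = "box")
  opened <- EBImage::opening(EBImage::Image(mask * 1), kern)
  labels <- .labels_8conn(opened)
  if (max(labels) == 0L) {
    comps <- data.frame(id = integer(), area = integer(),
                        centroid_x = numeric(), centroid_y = numeric())
    return(list(components = comps, labels = labels,
                background_lab = background_lab))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lv <- labels[labels > 0]
  area <- tabulate(lv)
  # centroids in 0-based pixel coordinates (x = col - 1, y = row - 1)
  cx <- tapply(idx[, 2] - 1, lv, mean)
  cy <- tapply(idx[, 1] - 1, lv, mean)
  comps <- data.frame(id = seq_along(area), area = area,
                      centroid_x = as.numeric(cx), centroid_y = as.numeric(cy))
  small <- comps$id[comps$area < min_area]
  if (length(small)) {
    labels[labels %in% small] <- 0L
    comps <- comps[!comps$id %in% small, , drop = FALSE]
  }
  list(components = comps, labels = labels, background_lab = background_lab)
}

#' Assign segmented components to tray wells
#'
#' Each component goes to the well whose grid cell contains its centroid;
#' a centroid lying exactly on a cell boundary goes to the lower-index cell.
#' Components whose centroid falls outside the grid are flagged
#' (`well_row = NA`) rather than dropped.
#'
#' @param segmentation result of [segment_kernels()].
#' @param layout a [tray_layout()].
#' @return the `components` data frame with added 0-based `well_row`,
#'   `well_col` columns.
#' @export
assign_wells <- function(segmentation, layout) {
  comps <- segmentation$components
  bb <- layout$tray_bbox
  cs <- .cell_size(layout)
  relx <- (comps$centroid_x - bb[1]) / cs["w"]
  rely <- (comps$centroid_y - bb[2]) / cs["h"]
  col <- pmax(0, ceiling(relx) - 1)
  row <- pmax(0, ceiling(rely) - 1)
  outside <- relx < 0 | rely < 0 | relx > layout$cols | rely > layout$rows
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  comps$well_row <- as.integer(row)
  comps$well_col <- as.integer(col)
  comps
}

#' Measure per-kernel color
#'
#' For each occupied well the component pixels (fragments in the same well
#' are merged into one kernel) are summarized by the 10% trimmed mean of L*,
#' a* and b*, which is robust to specular glare pixels.
#'
#' @param image the `calibrated_image` that was segmented.
#' @param assignment output of [assign_wells()].
#' @param labels label matrix from [segment_kernels()].
#' @param tray_id identifier recorded with each measurement.
#' @param trim trimming fraction for the per-kernel mean.
#' @return data frame with one row per occupied well: `tray_id, well_row,
#'   well_col, pixel_area, L, a, b`.
#' @export
measure_kernels <- function(image, assignment, labels, tray_id = "tray",
                            trim = 0.1) {
  ok <- !is.na(assignment$well_row)
  inside <- assignment[ok, , drop = FALSE]
  if (!nrow(inside)) {
    return(data.frame(tray_id = character(), well_row = integer(),
                      well_col = integer(), pixel_area = integer(),
                      L = numeric(), a = numeric(), b = numeric()))
  }
  img <- unclass(image)
  key <- paste(inside$well_row, inside$well_col)
  wells <- split(inside$id, key)
  out <- lapply(names(wells), function(k) {
    ids <- wells[[k]]
    pix <- which(matrix(labels %in% ids, nrow(labels), ncol(labels)))
    n <- length(pix)
    npix <- nrow(labels) * ncol(labels)
    rc <- as.integer(strsplit(k, " ")[[1]])
    data.frame(tray_id = tray_id, well_row = rc[1], well_col = rc[2],
               pixel_area = n,
               L = mean(img[pix], trim = trim),
               a = mean(img[pix + npix], trim = trim),
               b = mean(img[pix + 2 * npix], trim = trim))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$well_row, res$well_col), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Process a tray photograph end to end
#'
#' Composition of the full measurement pipeline: white-balance correction,
#' calibration to L*a*b*, kernel segmentation, well assignment, per-kernel
#' color measurement and DFA classification. Deterministic for fixed inputs.
#'
#' @param raw [rgb_image()] of the tray.
#' @param wb [rgb_image()] of the white-balance reference.
#' @param model fitted [fit_calibration()] model.
#' @param layout a [tray_layout()].
#' @param delta_e_threshold,min_area segmentation parameters, see
#'   [segment_kernels()].
#' @param dfa_cuts [dfa_thresholds()] used to classify each kernel.
#' @param tray_id identifier for the tray.
#' @param wb_method white-balance method, see [white_balance_correct()].
#' @return an object of class `tray_result`: list with `kernels` (data
#'   frame), `n_empty_wells`, `qc_flags`, `background_lab`, `tray_id`.
#' @export
process_tray <- function(raw, wb, model, layout, delta_e_threshold = 12,
                         min_area = NULL, dfa_cuts = dfa_thresholds(),
                         tray_id = "tray", wb_method = "flatfield") {
  corrected <- white_balance_correct(raw, wb, method = wb_method)
  cal <- apply_calibration(corrected, model)
  seg <- segment_kernels(cal, layout, delta_e_threshold = delta_e_threshold,
                         min_area = min_area)
  assignment <- assign_wells(seg, layout)
  kernels <- measure_kernels(cal, assignment, seg$labels, tray_id = tray_id)
  kernels$dfa_class <- if (nrow(kernels)) classify_dfa(kernels$L, dfa_cuts)
                       else integer()
  qc <- character()
  n_out <- sum(is.na(assignment$well_row))
  if (n_out) qc <- c(qc, sprintf("%d component(s) outside the well grid", n_out))
  dup <- sum(duplicated(paste(assignment$well_row, assignment$well_col),
                        incomparables = NA))
  if (dup) qc <- c(qc, sprintf("%d well(s) had merged fragments", dup))
  structure(list(tray_id = tray_id, kernels = kernels,
                 n_empty_wells = layout$rows * layout$cols - nrow(kernels),
                 qc_flags = qc, background_lab = seg$background_lab),
            class = "tray_result")
}

#' @export
print.tray_result <- function(x, ...) {
  cat(sprintf("<tray_result> '%s': %d kernels, %d empty wells\n",
              x$tray_id, nrow(x$kernels), x$n_empty_wells))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.tray_result <- function(object, ...) {
  k <- object$kernels
  cat(sprintf("Tray '%s': %d kernels (%d empty wells)\n", object$tray_id,
              nrow(k), object$n_empty_wells))
  if (nrow(k)) {
    cat(sprintf("  L* %.1f [%.1f, %.1f]  a* %.1f  b* %.1f  mean DFA %.2f\n",
                mean(k$L), min(k$L), max(k$L), mean(k$a), mean(k$b),
                mean(k$dfa_class)))
  }
  invisible(object)
}
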