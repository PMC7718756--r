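# Seeded synthetic-data generators: rendered tray and color-checker images
# with ground truth, bi-parental crosses with planted QTL, and
# pedigree-structured phenotypes with a stated heritability. Every
# generator is a pure function of its arguments and seed.

#' Render a synthetic tray image with known kernel colors
#'
#' Paints elliptical kernels of known L*a*b* color at the well centers of a
#' tray on a uniform background, converts to sRGB, applies a shared
#' multiplicative illumination gradient to both the tray and the
#' white-balance image (so WB correction is the mechanism under test), adds
#' Gaussian pixel noise and quantizes to 8 bits. Ground truth is the Lab
#' value actually painted (after sRGB gamut clipping).
#'
#' @param kernel_labs data frame `row, col, L, a, b` (0-based well indices)
#'   or an n x 3 Lab matrix filling wells in row-major order; `NULL` for an
#'   empty tray.
#' @param layout a [tray_layout()]; default a 10 x 10 grid with a 5% margin
#'   inside `image_size`.
#' @param image_size `c(height, width)` in pixels.
#' @param kernel_axes ellipse semi-axes `c(x, y)` in pixels; default 30% /
#'   22% of the well cell.
#' @param background_lab tray background color (default a bluish-gray
#'   commercial tray, Lab (45, 0, -15)).
#' @param noise_sigma Gaussian pixel noise SD in 8-bit units (default 2).
#' @param illum_gradient total fractional amplitude of a linear
#'   illumination gradient across the diagonal (default 0.05, i.e. +/-5%).
#' @param seed RNG seed.
#' @return list with `image` and `wb` ([rgb_image()]s), `truth` (data frame
#'   `row, col, L, a, b, clipped`), `layout` and `background_lab`.
#' @export
render_tray <- function(kernel_labs = NULL, layout = NULL,
                        image_size = c(500, 500), kernel_axes = NULL,
                        background_lab = c(45, 0, -15), noise_sigma = 2,
                        illum_gradient = 0.05, seed = 1L) {
  H <- image_size[1]; W <- image_size[2]
  if (is.null(layout)) {
    mx <- round(0.05 * W); my <- round(0.05 * H)
    layout <- tray_layout(10L, 10L, c(mx, my, W - mx, H - my),
                          background_lab = background_lab)
  }
  cs <- .cell_size(layout)
  if (is.null(kernel_axes))
    kernel_axes <- c(0.30 * cs[["w"]], 0.22 * cs[["h"]])
  if (!is.null(kernel_labs) && is.null(dim(kernel_labs)))
    kernel_labs <- matrix(kernel_labs, ncol = 3, byrow = TRUE)
  if (!is.null(kernel_labs) && !is.data.frame(kernel_labs)) {
    m <- as.matrix(kernel_labs)
    if (nrow(m) > layout$rows * layout$cols)
      stop("more kernels than wells", call. = FALSE)
    idx <- seq_len(nrow(m)) - 1L
    kernel_labs <- data.frame(row = idx %/% layout$cols,
                              col = idx %% layout$cols,
                              L = m[, 1], a = m[, 2], b = m[, 3])
  }
  set.seed(seed)
  lab_img <- array(rep(background_lab, each = H * W), c(H, W, 3))
  truth <- data.frame(row = integer(), col = integer(), L = numeric(),
                      a = numeric(), b = numeric(), clipped = logical())
  if (!is.null(kernel_labs) && nrow(kernel_labs)) {
    xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
    ys <- matrix(rep(seq_len(H) - 0.5, W), H, W)
    for (k in seq_len(nrow(kernel_labs))) {
      r <- kernel_labs$row[k]; cl <- kernel_labs$col[k]
      cx <- layout$tray_bbox[1] + (cl + 0.5) * cs[["w"]]
      cy <- layout$tray_bbox[2] + (r + 0.5) * cs[["h"]]
      inside <- ((xs - cx) / kernel_axes[1])^2 +
                ((ys - cy) / kernel_axes[2])^2 <= 1
      want <- c(kernel_labs$L[k], kernel_labs$a[k], kernel_labs$b[k])
      srgb <- lab_to_srgb(want)
      painted <- srgb_to_lab(srgb)       # gamut-clipped ground truth
      for (ch in 1:3) {
        plane <- lab_img[, , ch]
        plane[inside] <- painted[ch]
        lab_img[, , ch] <- plane
      }
      truth <- rbind(truth, data.frame(row = r, col = cl, L = painted[1],
                                       a = painted[2], b = painted[3],
                                       clipped = attr(srgb, "clipped")))
    }
  }
  pix <- matrix(as.numeric(lab_img), H * W, 3)
  srgb <- lab_to_srgb(pix)
  img <- array(srgb, c(H, W, 3))
  xn <- matrix(rep((seq_len(W) - 1) / max(W - 1, 1), each = H), H, W)
  yn <- matrix(rep((seq_len(H) - 1) / max(H - 1, 1), W), H, W)
  field <- 1 + illum_gradient * ((xn - 0.5) + (yn - 0.5))
  wb <- array(255, c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * field
    wb[, , ch] <- wb[, , ch] * field
  }
  if (noise_sigma > 0) {
    img <- img + array(stats::rnorm(H * W * 3, 0, noise_sigma), c(H, W, 3))
    wb <- wb + array(stats::rnorm(H * W * 3, 0, noise_sigma), c(H, W, 3))
  }
  img <- round(pmin(pmax(img, 0), 255))
  wb <- round(pmin(pmax(wb, 0), 255))
  if (any(truth$clipped))
    warning(sum(truth$clipped), " kernel color(s) outside the sRGB gamut ",
            "were clipped", call. = FALSE)
  list(image = rgb_image(img), wb = rgb_image(wb), truth = truth,
       layout = layout, background_lab = background_lab)
}

#' Default 24-patch checker reference
#'
#' A 6 x 4 grid of patches targeted at the pellicle working gamut: 18
#' brown/amber/yellow tones spanning the range of kernel colors plus a
#' 6-step neutral ramp. Reference Lab values are derived from the fixed
#' sRGB patch colors through [srgb_to_lab()]; concentrating the chart on
#' the working gamut is what lets a low-order polynomial calibration reach
#' sub-dE accuracy where it matters.
#'
#' @param patch_px,gap_px patch size and spacing in pixels.
#' @return a [checker_reference()].
#' @export
default_checker_reference <- function(patch_px = 40, gap_px = 10) {
  wal <- as.matrix(expand.grid(R = c(90, 140, 190, 230),
                               G = c(70, 110, 150, 190),
                               B = c(40, 80, 120)))
  wal <- wal[wal[, 1] >= wal[, 2] & wal[, 2] >= wal[, 3] - 20, ,
             drop = FALSE][1:18, ]
  neut <- matrix(rep(seq(30, 230, length.out = 6), 3), ncol = 3)
  rgbs <- rbind(wal, neut)
  labs <- srgb_to_lab(rgbs)
  regions <- do.call(rbind, lapply(0:23, function(i) {
    r <- i %/% 6; cl <- i %% 6
    x0 <- gap_px + cl * (patch_px + gap_px)
    y0 <- gap_px + r * (patch_px + gap_px)
    data.frame(x0 = x0, y0 = y0, x1 = x0 + patch_px, y1 = y0 + patch_px)
  }))
  checker_reference(sprintf("P%02d", 1:24), regions, labs)
}

#' Render a synthetic color-checker image
#'
#' Patches are painted from the reference Lab values via [lab_to_srgb()]
#' on a mid-gray canvas, with optional Gaussian noise.
#'
#' @param reference a [checker_reference()].
#' @param noise_sigma pixel noise SD (8-bit units).
#' @param seed RNG seed.
#' @return an [rgb_image()].
#' @export
render_checker <- function(reference = default_checker_reference(),
                           noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(reference, "checker_reference"))
  if (!nrow(reference$patch_regions))
    stop("empty checker reference", call. = FALSE)
  set.seed(seed)
  W <- max(reference$patch_regions$x1) + 10
  H <- max(reference$patch_regions$y1) + 10
  img <- array(128, c(H, W, 3))
  srgb <- lab_to_srgb(reference$reference_labs)
  for (i in seq_len(nrow(reference$patch_regions))) {
    r <- reference$patch_regions[i, ]
    rows <- (r$y0 + 1):r$y1; cols <- (r$x0 + 1):r$x1
    for (ch in 1:3) img[rows, cols, ch] <- srgb[i, ch]
  }
  if (noise_sigma > 0)
    img <- img + array(stats::rnorm(H * W * 3, 0, noise_sigma), c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255))
  rgb_image(img)
}

#' Simulate a genetic map
#'
#' Uniformly spaced-ish markers (jittered) per linkage group with a linear
#' cM-to-bp relation, emulating the density of a walnut parental map.
#'
#' @param n_groups number of linkage groups.
#' @param markers_per_group markers on each group.
#' @param length_cM group length.
#' @param bp_per_cM physical scale (default 300 kb per cM).
#' @param seed RNG seed.
#' @return a [genetic_map()].
#' @export
simulate_genetic_map <- function(n_groups = 2, markers_per_group = 40,
                                 length_cM = 60, bp_per_cM = 3e5,
                                 seed = 1L) {
  set.seed(seed)
  maps <- lapply(seq_len(n_groups), function(g) {
    pos <- sort(c(0, length_cM,
                  stats::runif(markers_per_group - 2, 0, length_cM)))
    data.frame(group = sprintf("LG%d", g),
               marker = sprintf("M%d_%d", g, seq_along(pos)),
               cM = pos, bp = round(pos * bp_per_cM + 1))
  })
  df <- do.call(rbind, maps)
  genetic_map(df$group, df$marker, df$cM, df$bp)
}

#' Simulate a pseudo-testcross progeny set with planted QTL
#'
#' Progeny genotypes follow a two-state Markov chain along each linkage
#' group with Haldane recombination between adjacent positions. The
#' phenotype is the sum of the planted additive QTL effects (expressed in
#' residual-SD units, added when the QTL genotype is `A`) plus Gaussian
#' residual noise. Genotypes are masked at `missing_rate`.
#'
#' @param map a [genetic_map()].
#' @param n_progeny number of individuals (default 168, the size of a
#'   typical bi-parental walnut mapping population).
#' @param qtl data frame `group, pos, effect` (effect in residual SD);
#'   `NULL` for a null trait.
#' @param residual_sd residual standard deviation.
#' @param missing_rate fraction of genotypes masked to `NA`.
#' @param seed RNG seed.
#' @return list with `genotypes` ([genotype_matrix()]), `phenotype`
#'   (numeric), and `truth` (planted QTL with snapped positions).
#' @export
simulate_cross <- function(map, n_progeny = 168, qtl = NULL,
                           residual_sd = 1, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    for (k in seq_len(nrow(qtl))) {
      sub <- map[map$group == qtl$group[k], , drop = FALSE]
      if (!nrow(sub) || qtl$pos[k] < min(sub$cM) || qtl$pos[k] > max(sub$cM))
        stop(sprintf("QTL %d lies off the map", k), call. = FALSE)
    }
  }
  set.seed(seed)
  groups <- unique(map$group)
  geno_cols <- list()
  qtl_geno <- matrix(0, n_progeny, if (is.null(qtl)) 0 else nrow(qtl))
  for (g in groups) {
    sub <- map[map$group == g, , drop = FALSE]
    qpos <- if (is.null(qtl)) numeric() else qtl$pos[qtl$group == g]
    pos <- sort(unique(c(sub$cM, qpos)))
    r <- recomb_fraction(diff(pos))
    G <- matrix(0L, n_progeny, length(pos))
    G[, 1] <- stats::rbinom(n_progeny, 1, 0.5)
    for (j in seq_along(r)) {
      swap <- stats::rbinom(n_progeny, 1, r[j]) == 1
      G[, j + 1] <- ifelse(swap, 1L - G[, j], G[, j])
    }
    mcols <- G[, match(sub$cM, pos), drop = FALSE]
    colnames(mcols) <- sub$marker
    geno_cols[[g]] <- mcols
    if (length(qpos)) {
      which_q <- which(qtl$group == g)
      qtl_geno[, which_q] <- G[, match(qpos, pos), drop = FALSE]
    }
  }
  G <- do.call(cbind, geno_cols)
  y <- stats::rnorm(n_progeny, 0, residual_sd)
  if (!is.null(qtl) && nrow(qtl))
    y <- y + as.numeric(qtl_geno %*% (qtl$effect * residual_sd))
  codes <- matrix(ifelse(G == 1L, "A", "H"), nrow(G), ncol(G),
                  dimnames = list(sprintf("ind%03d", seq_len(n_progeny)),
                                  colnames(G)))
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(codes)) < missing_rate,
                   nrow(codes), ncol(codes))
    codes[mask] <- NA_character_
  }
  list(genotypes = genotype_matrix(codes), phenotype = y,
       truth = list(qtl = qtl, residual_sd = residual_sd))
}

#' Simulate pedigree-structured phenotypes with stated heritability
#'
#' Builds a multi-generation pedigree (each generation mates disjoint
#' random pairs of the previous one, `family_size` offspring per pair) and
#' simulates breeding values under the additive infinitesimal model:
#' founder BV ~ N(0, h2 sigma^2), offspring BV = parent average + Mendelian
#' sampling N(0, h2 sigma^2 / 2) (non-inbred parents), phenotype = mean +
#' BV + N(0, (1 - h2) sigma^2).
#'
#' @param n_founders number of unrelated founders (default 20, as in a
#'   walnut breeding-program founder set).
#' @param n_generations generations bred from the founders.
#' @param family_size full-sib family size.
#' @param h2_true simulated narrow-sense heritability (default 0.56).
#' @param mean,phenotype_sd phenotype location and total SD.
#' @param seed RNG seed.
#' @return list with `ped` ([pedigree()]), `phenotype` (named vector, all
#'   individuals) and `breeding_values` (true BV).
#' @export
simulate_pedigree_phenotypes <- function(n_founders = 20, n_generations = 2,
                                         family_size = 10, h2_true = 0.56,
                                         mean = 0, phenotype_sd = 1,
                                         seed = 1L) {
  stopifnot(h2_true >= 0, h2_true <= 1, n_founders >= 2)
  set.seed(seed)
  s2 <- phenotype_sd^2
  id <- sprintf("F%03d", seq_len(n_founders))
  sire <- dam <- rep(NA_character_, n_founders)
  bv <- stats::rnorm(n_founders, 0, sqrt(h2_true * s2))
  names(bv) <- id
  prev <- id
  counter <- 0L
  for (gen in seq_len(n_generations)) {
    pool <- sample(prev)
    n_pairs <- floor(length(pool) / 2)
    newgen <- character()
    for (k in seq_len(n_pairs)) {
      p1 <- pool[2 * k - 1]; p2 <- pool[2 * k]
      for (o in seq_len(family_size)) {
        counter <- counter + 1L
        child <- sprintf("G%d_%04d", gen, counter)
        id <- c(id, child); sire <- c(sire, p1); dam <- c(dam, p2)
        bv[child] <- (bv[p1] + bv[p2]) / 2 +
          stats::rnorm(1, 0, sqrt(h2_true * s2 / 2))
        newgen <- c(newgen, child)
      }
    }
    prev <- newgen
  }
  ped <- pedigree(id, sire, dam)
  bv <- bv[ped$id]
  y <- mean + bv + stats::rnorm(length(bv), 0, sqrt((1 - h2_true) * s2))
  names(y) <- ped$id
  list(ped = ped, phenotype = y, breeding_values = bv)
}
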