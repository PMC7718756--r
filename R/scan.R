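# Haley-Knott interval mapping: genome scan, permutation thresholds,
# genome-wide p-values, Bayes credible intervals, multi-QTL fits and
# position refinement.

.check_pheno <- function(probs, phenotype) {
  n <- nrow(probs$groups[[1]]$probA)
  if (length(phenotype) != n)
    stop("phenotype length does not match the genotyped individuals",
         call. = FALSE)
  if (stats::sd(phenotype, na.rm = TRUE) == 0 ||
      sum(!is.na(phenotype)) < 3)
    stop("phenotype is constant or has too few observations", call. = FALSE)
  invisible(n)
}

# Stack the per-group probability matrices into one n x positions matrix
# plus a position index (group, pos).
.stack_probs <- function(probs) {
  mats <- lapply(probs$groups, `[[`, "probA")
  index <- do.call(rbind, lapply(names(probs$groups), function(g) {
    data.frame(group = g, pos = probs$groups[[g]]$pos,
               stringsAsFactors = FALSE)
  }))
  list(P = do.call(cbind, mats), index = index)
}

# LOD of the regression of y on one predictor column with intercept:
# LOD = -(n/2) log10(1 - r^2). Vectorized over the columns of P.
.lod_columns <- function(P, y) {
  n <- length(y)
  r <- suppressWarnings(stats::cor(P, y))
  r[is.na(r)] <- 0                       # constant predictor: no information
  pmax(0, -(n / 2) * log10(1 - r^2))
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At every grid position the phenotype is regressed on the conditional
#' probability of the `A` genotype; the LOD score is
#' `(n/2) log10(RSS0 / RSS1)` comparing against the intercept-only model.
#'
#' @param probs genotype probabilities from [genotype_probs()].
#' @param phenotype numeric phenotype, one value per individual (NAs
#'   dropped).
#' @return an object of class `qtl_scan`: data frame `group, pos, lod` with
#'   attributes recording `n` and the peak per group. Has `print`,
#'   `summary` and `plot` methods.
#' @export
scanone_hk <- function(probs, phenotype) {
  .check_pheno(probs, phenotype)
  keep <- !is.na(phenotype)
  sp <- .stack_probs(probs)
  lod <- .lod_columns(sp$P[keep, , drop = FALSE], phenotype[keep])
  out <- sp$index
  out$lod <- as.numeric(lod)
  structure(out, class = c("qtl_scan", "data.frame"),
            n = sum(keep), step_cM = probs$step_cM)
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("<qtl_scan> %d positions on %d group(s), n = %d\n",
              nrow(x), length(unique(x$group)), attr(x, "n")))
  print(summary(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, threshold = NULL, ...) {
  peaks <- do.call(rbind, lapply(split(seq_len(nrow(object)), object$group),
    function(i) {
      j <- i[which.max(object$lod[i])]   # which.max: leftmost tie
      object[j, c("group", "pos", "lod")]
    }))
  peaks <- as.data.frame(peaks)
  class(peaks) <- "data.frame"
  rownames(peaks) <- NULL
  if (!is.null(threshold))
    peaks <- peaks[peaks$lod >= threshold, , drop = FALSE]
  peaks
}

#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  groups <- unique(x$group)
  offs <- 0
  xs <- numeric(nrow(x))
  ticks <- numeric(length(groups))
  for (k in seq_along(groups)) {
    i <- x$group == groups[k]
    xs[i] <- x$pos[i] + offs
    ticks[k] <- offs + mean(range(x$pos[i]))
    offs <- offs + max(x$pos[i]) + 10
  }
  graphics::plot(xs, x$lod, type = "n", xaxt = "n", xlab = "linkage group",
                 ylab = "LOD", ...)
  for (k in seq_along(groups)) {
    i <- x$group == groups[k]
    graphics::lines(xs[i], x$lod[i])
  }
  graphics::axis(1, at = ticks, labels = groups)
  if (!is.null(threshold))
    graphics::abline(h = threshold, lty = 2, col = "red")
  invisible(x)
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype against the genotype rows, rescans, and returns
#' the empirical `1 - alpha` quantile of the genome-wide maximum LOD.
#' Reproducible for a fixed `seed`.
#'
#' @param probs genotype probabilities from [genotype_probs()].
#' @param phenotype numeric phenotype vector.
#' @param n_perm number of permutations (1000 for final inference; at least
#'   100).
#' @param alpha genome-wide type-I error rate.
#' @param seed RNG seed.
#' @return an object of class `qtl_perm`: list with `threshold`, `alpha`,
#'   `max_lods` (the permutation sample), `n_perm`, `seed`.
#' @export
permutation_threshold <- function(probs, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1L) {
  if (n_perm < 100) stop("use at least 100 permutations", call. = FALSE)
  .check_pheno(probs, phenotype)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  sp <- .stack_probs(probs)
  P <- sp$P[keep, , drop = FALSE]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  n <- length(y)
  R <- suppressWarnings(stats::cor(P, Y))
  R[is.na(R)] <- 0
  lods <- -(n / 2) * log10(1 - R^2)
  lods[lods < 0] <- 0
  max_lods <- apply(lods, 2, max)
  structure(list(threshold = stats::quantile(max_lods, 1 - alpha,
                                             names = FALSE),
                 alpha = alpha, max_lods = max_lods, n_perm = n_perm,
                 seed = seed),
            class = "qtl_perm")
}

#' @export
print.qtl_perm <- function(x, ...) {
  cat(sprintf("<qtl_perm> %d permutations: LOD threshold %.3f at alpha %.3g\n",
              x$n_perm, x$threshold, x$alpha))
  invisible(x)
}

#' Genome-wide p-value from the permutation distribution
#'
#' The plus-one empirical rule: `p = (1 + #permutations >= observed) /
#' (n_perm + 1)`.
#'
#' @param max_lod observed genome-wide maximum LOD (or a peak LOD).
#' @param perm a `qtl_perm` object or a numeric permutation sample.
#' @return genome-wide p-value.
#' @export
lod_to_pvalue <- function(max_lod, perm) {
  sample <- if (inherits(perm, "qtl_perm")) perm$max_lods else perm
  if (!length(sample)) stop("empty permutation sample", call. = FALSE)
  (1 + sum(sample >= max_lod)) / (length(sample) + 1)
}

#' Bayes credible interval for a QTL position
#'
#' Treats the normalized `10^LOD` profile on one linkage group as a
#' posterior over position and returns the smallest contiguous run of grid
#' points containing the peak whose mass reaches `coverage` (exact
#' enumeration over all windows containing the peak; among minimal-length
#' windows the one with the largest mass is taken). Physical (bp) endpoints
#' are interpolated from the map when it carries bp positions.
#'
#' @param scan a `qtl_scan` (or data frame with `group, pos, lod`).
#' @param group which linkage group.
#' @param coverage posterior mass to cover (default 0.95).
#' @param map optional [genetic_map()] with `bp` for physical interpolation.
#' @return list with `low_cM`, `high_cM`, `peak_cM`, `mass` and, when bp
#'   available, `low_bp`, `high_bp`, `peak_bp`.
#' @export
bayes_interval <- function(scan, group, coverage = 0.95, map = NULL) {
  g <- scan[scan$group == group, , drop = FALSE]
  if (!nrow(g)) stop(sprintf("no positions on group '%s'", group),
                     call. = FALSE)
  w <- 10^(g$lod - max(g$lod))
  w <- w / sum(w)
  peak <- which.max(g$lod)
  cw <- c(0, cumsum(w))
  best <- NULL
  for (i in seq_len(peak)) {
    for (j in peak:length(w)) {
      mass <- cw[j + 1] - cw[i]
      if (mass >= coverage - 1e-12) {
        len <- j - i
        if (is.null(best) || len < best$len ||
            (len == best$len && mass > best$mass))
          best <- list(i = i, j = j, len = len, mass = mass)
        break                            # wider j only adds length
      }
    }
  }
  if (is.null(best)) best <- list(i = 1, j = length(w), len = length(w) - 1,
                                  mass = 1)
  out <- list(group = group, low_cM = g$pos[best$i], high_cM = g$pos[best$j],
              peak_cM = g$pos[peak], mass = best$mass)
  if (!is.null(map) && "bp" %in% names(map)) {
    sub <- map[map$group == group & !is.na(map$bp), , drop = FALSE]
    if (nrow(sub) >= 2) {
      interp <- stats::approx(sub$cM, sub$bp,
                              xout = c(out$low_cM, out$high_cM, out$peak_cM),
                              rule = 2, ties = mean)$y
      out$low_bp <- interp[1]; out$high_bp <- interp[2]
      out$peak_bp <- interp[3]
    }
  }
  out
}

# Probability columns at the grid positions nearest to the requested
# (group, pos) pairs.
.qtl_design <- function(probs, positions) {
  cols <- lapply(seq_len(nrow(positions)), function(k) {
    g <- probs$groups[[as.character(positions$group[k])]]
    if (is.null(g))
      stop(sprintf("no such linkage group: %s", positions$group[k]),
           call. = FALSE)
    j <- which.min(abs(g$pos - positions$pos[k]))
    list(col = g$probA[, j], pos = g$pos[j])
  })
  list(X = do.call(cbind, lapply(cols, `[[`, "col")),
       snapped = vapply(cols, `[[`, numeric(1), "pos"))
}

#' Multiple-QTL Haley-Knott fit
#'
#' Joint regression of the phenotype on the genotype probabilities of
#' several QTL positions, with a drop-one analysis per QTL: each QTL's LOD
#' and p-value compare the full model against the model without that QTL,
#' and its variance explained is `SS_drop / SS_total`. The joint model's
#' `R^2 = SS_model / SS_total`.
#'
#' @param probs genotype probabilities from [genotype_probs()].
#' @param phenotype numeric phenotype vector.
#' @param positions data frame `group, pos` of QTL to fit.
#' @return an object of class `qtl_fit`: `joint` (n, lod, r2, p) and
#'   `per_qtl` data frame (group, pos, lod, r2, p).
#' @export
fit_multi_qtl <- function(probs, phenotype, positions) {
  if (!nrow(positions)) stop("supply at least one QTL position",
                             call. = FALSE)
  .check_pheno(probs, phenotype)
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  n <- length(y)
  des <- .qtl_design(probs, positions)
  X <- des$X[keep, , drop = FALSE]
  for (a in seq_len(nrow(positions))) for (b in seq_len(nrow(positions))) {
    if (a < b && positions$group[a] == positions$group[b] &&
        abs(des$snapped[a] - des$snapped[b]) < 1)
      warning("QTL positions < 1 cM apart: near-collinear design",
              call. = FALSE)
  }
  rss <- function(M) {
    fit <- stats::lm.fit(cbind(1, M), y)
    sum(fit$residuals^2)
  }
  rss0 <- sum((y - mean(y))^2)
  rss_full <- rss(X)
  k_full <- ncol(X)
  joint_lod <- (n / 2) * log10(rss0 / rss_full)
  f_joint <- ((rss0 - rss_full) / k_full) / (rss_full / (n - k_full - 1))
  joint <- list(n = n, lod = joint_lod, r2 = 1 - rss_full / rss0,
                p = stats::pf(f_joint, k_full, n - k_full - 1,
                              lower.tail = FALSE))
  per <- lapply(seq_len(ncol(X)), function(k) {
    rss_d <- if (ncol(X) == 1L) rss0 else rss(X[, -k, drop = FALSE])
    lod <- (n / 2) * log10(rss_d / rss_full)
    fstat <- (rss_d - rss_full) / (rss_full / (n - k_full - 1))
    data.frame(group = positions$group[k], pos = des$snapped[k], lod = lod,
               r2 = (rss_d - rss_full) / rss0,
               p = stats::pf(fstat, 1, n - k_full - 1, lower.tail = FALSE))
  })
  structure(list(joint = joint, per_qtl = do.call(rbind, per)),
            class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat(sprintf("<qtl_fit> %d QTL, joint LOD %.3f, joint R2 %.3f\n",
              nrow(x$per_qtl), x$joint$lod, x$joint$r2))
  print(x$per_qtl, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Refine multiple-QTL positions
#'
#' Coordinate-wise grid search: each QTL in turn is moved along its linkage
#' group to the position maximizing the joint LOD while the others are held
#' fixed, iterating until no position changes. The joint LOD is
#' non-decreasing across iterations.
#'
#' @param probs genotype probabilities from [genotype_probs()].
#' @param phenotype numeric phenotype vector.
#' @param positions data frame `group, pos` of starting positions (e.g. the
#'   scan peaks).
#' @param max_iter safety cap on sweeps.
#' @return the refined `positions` data frame with a `"joint_lod"`
#'   attribute.
#' @export
refine_positions <- function(probs, phenotype, positions, max_iter = 20) {
  keep <- !is.na(phenotype)
  y <- phenotype[keep]
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  joint_lod <- function(pos_df) {
    X <- .qtl_design(probs, pos_df)$X[keep, , drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    (n / 2) * log10(rss0 / sum(fit$residuals^2))
  }
  positions <- as.data.frame(positions)
  current <- joint_lod(positions)
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (k in seq_len(nrow(positions))) {
      g <- probs$groups[[as.character(positions$group[k])]]
      cand <- positions
      lods <- vapply(g$pos, function(p) {
        cand$pos[k] <- p
        joint_lod(cand)
      }, numeric(1))
      best <- which.max(lods)
      if (lods[best] > current + 1e-9) {
        positions$pos[k] <- g$pos[best]
        current <- lods[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  attr(positions, "joint_lod") <- current
  positions
}
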