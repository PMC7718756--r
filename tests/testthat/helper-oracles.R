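# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (base R, brute force or enumeration) than
# the package code.

# grDevices-based sRGB -> Lab reference (independent of the package's
# conversion code).
oracle_srgb_to_lab <- function(rgb) {
  grDevices::convertColor(matrix(rgb / 255, ncol = 3), from = "sRGB",
                          to = "Lab")
}

# Single-marker regression LOD via lm(), the brute-force Haley-Knott
# oracle at a typed marker.
oracle_marker_lod <- function(y, x) {
  fit1 <- stats::lm(y ~ x)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::residuals(fit1)^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Recursive definition of the additive relationship (memoised), applied to
# a pedigree data frame in any order.
oracle_amatrix <- function(ped) {
  ids <- ped$id
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  gen_depth <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    s <- sire[i]; d <- dam[i]
    depth[i] <<- 1L + max(if (is.na(s)) 0L else gen_depth(s),
                          if (is.na(d)) 0L else gen_depth(d))
    depth[i]
  }
  for (i in ids) gen_depth(i)
  memo <- new.env()
  a <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      1 + 0.5 * a(sire[[i]], dam[[i]])
    } else {
      # recurse on the individual further from the founders
      k <- if (depth[[i]] >= depth[[j]]) i else j
      o <- if (k == i) j else i
      0.5 * (a(sire[[k]], o) + a(dam[[k]], o))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ids) for (j in ids) A[i, j] <- a(i, j)
  A
}

# Random valid pedigree topology on n individuals (parents drawn among
# earlier individuals or unknown).
random_pedigree <- function(n, p_known = 0.7) {
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3 && stats::runif(1) < p_known) {
      par <- sample(id[seq_len(i - 1)], 2, replace = FALSE)
      sire[i] <- par[1]; dam[i] <- par[2]
    }
  }
  pedigree(id, sire, dam)
}

# Brute-force SNP quality-control tally mirroring the documented filter
# order with plain loops.
oracle_snp_qc <- function(g, maf_min = 0.05, cr_min = 0.90,
                          hwe_min = 0.001) {
  keep_ind <- logical(nrow(g))
  for (i in seq_len(nrow(g)))
    keep_ind[i] <- mean(!is.na(g[i, ])) >= cr_min
  g1 <- g[keep_ind, , drop = FALSE]
  keep_maf <- logical(ncol(g1))
  for (j in seq_len(ncol(g1))) {
    x <- g1[, j]; x <- x[!is.na(x)]
    p <- if (length(x)) sum(x) / (2 * length(x)) else 0
    keep_maf[j] <- min(p, 1 - p) >= maf_min
  }
  g2 <- g1[, keep_maf, drop = FALSE]
  keep_hwe <- logical(ncol(g2))
  for (j in seq_len(ncol(g2))) {
    x <- g2[, j]; x <- x[!is.na(x)]
    n <- length(x)
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    p <- (2 * obs[3] + obs[2]) / (2 * n)
    if (p == 0 || p == 1) { keep_hwe[j] <- TRUE; next }
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    pv <- stats::pchisq(sum((obs - e)^2 / e), 1, lower.tail = FALSE)
    keep_hwe[j] <- pv >= hwe_min
  }
  g2[, keep_hwe, drop = FALSE]
}

# Matrix forward-backward for the two-state marker chain: marginal P(A) at
# position p given observed markers (positions pos, genotypes g in {1 = A,
# 0 = H}), Haldane transitions. Independent of the package's closed form.
oracle_prob_A <- function(p, pos, g) {
  all_pos <- sort(unique(c(pos, p)))
  k <- length(all_pos)
  trans <- function(d) {
    r <- (1 - exp(-2 * d / 100)) / 2
    matrix(c(1 - r, r, r, 1 - r), 2, 2)
  }
  emit <- function(q) {
    j <- match(all_pos[q], pos)
    if (is.na(j)) return(c(1, 1))
    if (g[j] == 1) c(1, 0) else c(0, 1)   # state order (A, H)
  }
  fwd <- matrix(0, k, 2)
  fwd[1, ] <- c(0.5, 0.5) * emit(1)
  if (k > 1) for (q in 2:k)
    fwd[q, ] <- (fwd[q - 1, ] %*% trans(all_pos[q] - all_pos[q - 1])) *
      emit(q)
  bwd <- matrix(0, k, 2)
  bwd[k, ] <- c(1, 1)
  if (k > 1) for (q in (k - 1):1)
    bwd[q, ] <- trans(all_pos[q + 1] - all_pos[q]) %*%
      (emit(q + 1) * bwd[q + 1, ])
  i <- match(p, all_pos)
  post <- fwd[i, ] * bwd[i, ]
  post[1] / sum(post)
}

# Smallest contiguous credible window containing the peak, by naive
# enumeration with explicit sums.
oracle_bayes_window <- function(lod, coverage = 0.95) {
  w <- 10^(lod - max(lod)); w <- w / sum(w)
  peak <- which.max(lod)
  best <- NULL
  for (i in 1:peak) for (j in peak:length(w)) {
    mass <- sum(w[i:j])
    if (mass >= coverage - 1e-12) {
      len <- j - i
      if (is.null(best) || len < best["len"] ||
          (len == best["len"] && mass > best["mass"]))
        best <- c(i = i, j = j, len = len, mass = mass)
    }
  }
  if (is.null(best)) c(i = 1, j = length(w), len = length(w) - 1, mass = 1)
  else best
}

# Small phenotype table builder for the ANOVA / adjusted-means tests.
make_pheno_table <- function(values, tree, family, year, age = 0,
                             trait = "L") {
  data.frame(tree_id = tree, family = family, year = year, age = age,
             trait = trait, value = values)
}
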