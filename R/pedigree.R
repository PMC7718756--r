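# Pedigree machinery: additive relationship matrix (tabular method),
# EM-REML variance components / narrow-sense heritability, and BLUP
# breeding values from Henderson's mixed-model equations.

#' Pedigree
#'
#' Records of individual, sire and dam (unknown parents `NA`, `0` or `""`).
#' Validated to be acyclic and returned in topological order (parents
#' before offspring).
#'
#' @param id,sire,dam vectors of identifiers.
#' @return data frame of class `pedigree` with character columns
#'   `id, sire, dam` (unknown parent = `NA`).
#' @export
pedigree <- function(id, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  df <- data.frame(id = as.character(id), sire = norm(sire), dam = norm(dam))
  if (anyDuplicated(df$id)) stop("duplicate individual ids", call. = FALSE)
  unknown <- setdiff(c(df$sire, df$dam), c(df$id, NA))
  if (length(unknown))
    stop("parents absent from the pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  # Kahn topological sort; failure to exhaust the list means a cycle.
  placed <- character()
  remaining <- df
  ord <- integer()
  while (nrow(remaining)) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
             (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready))
      stop("pedigree contains a cycle (an individual is its own ancestor)",
           call. = FALSE)
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  df <- df[match(placed, df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Additive (numerator) relationship matrix
#'
#' Wright's A matrix by the tabular method: individuals in topological
#' order, `A[i,i] = 1 + F_i` with inbreeding `F_i = A[sire, dam] / 2`, and
#' `A[i,j] = (A[j, sire(i)] + A[j, dam(i)]) / 2` for `j` preceding `i`.
#' Symmetric positive semidefinite.
#'
#' @param ped a [pedigree()].
#' @return the q x q relationship matrix with ids as dimnames.
#' @export
amatrix <- function(ped) {
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped$id, ped$sire, ped$dam)
  q <- nrow(ped)
  A <- matrix(0, q, q, dimnames = list(ped$id, ped$id))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  for (i in seq_len(q)) {
    s <- si[i]; d <- di[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[j, s] else rep(0, i - 1)
      ad_ <- if (!is.na(d)) A[j, d] else rep(0, i - 1)
      A[i, j] <- A[j, i] <- (as_ + ad_) / 2
    }
  }
  A
}

#' Narrow-sense heritability by EM-REML
#'
#' Fits the animal model `y = X tau + Z u + e` with `var(u) = sigma2_A * A`
#' and `var(e) = sigma2_R * I` by EM-REML on error contrasts: the data are
#' rotated to the eigenbasis of the projected covariance `Q' Z A Z' Q`
#' (with `Q` an orthonormal basis of the complement of `X`), where the EM
#' update costs O(n) per iteration. Narrow-sense heritability is
#' `h2 = sigma2_A / (sigma2_A + sigma2_R)`, with approximate standard
#' errors from the inverse expected information and the delta method.
#'
#' @param y phenotype vector (one record per row of `Z`).
#' @param A additive relationship matrix from [amatrix()] (or any psd
#'   covariance structure).
#' @param X fixed-effect design matrix; default an intercept. Must be full
#'   column rank.
#' @param Z incidence matrix mapping records to the rows of `A`; default
#'   identity (one record per individual, in `A`'s order).
#' @param max_iter,tol EM iteration cap (500) and relative convergence
#'   tolerance (1e-6).
#' @return object of class `reml_fit`: `sigma2_A`, `sigma2_R`, `h2`,
#'   `se_h2`, `se_sigma2` (length 2), `converged`, `iterations`,
#'   `loglik` (restricted), plus the inputs needed by
#'   [blup_breeding_values()].
#' @export
reml_h2 <- function(y, A, X = NULL, Z = NULL, max_iter = 500, tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("X must be full column rank", call. = FALSE)
  if (is.null(Z)) {
    if (nrow(A) != n) stop("with Z = identity, A must be n x n",
                           call. = FALSE)
    K <- A
  } else {
    Z <- as.matrix(Z)
    K <- Z %*% A %*% t(Z)
  }
  p <- ncol(X)
  m <- n - p
  # error contrasts: columns p+1..n of the complete Q of qr(X)
  Q2 <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- crossprod(Q2, K %*% Q2)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  eta <- as.numeric(crossprod(eg$vectors, crossprod(Q2, y)))
  vy <- stats::var(y)
  if (vy == 0) vy <- 1e-8
  sA <- sR <- vy / 2
  pos <- xi > 1e-10
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    v <- sA * xi + sR
    a_hat <- sA * xi / v * eta
    a_var <- sA * xi * sR / v
    e_hat <- eta - a_hat
    sA_new <- sum((a_hat^2 + a_var)[pos] / xi[pos]) / sum(pos)
    sR_new <- sum(e_hat^2 + a_var) / m
    rel <- max(abs(sA_new - sA), abs(sR_new - sR)) / max(sA + sR, 1e-12)
    sA <- sA_new; sR <- sR_new
    if (rel < tol) { converged <- TRUE; break }
  }
  v <- sA * xi + sR
  loglik <- -0.5 * sum(log(v) + eta^2 / v)
  # expected information for (sigma2_A, sigma2_R) in the rotated model
  info <- 0.5 * matrix(c(sum(xi^2 / v^2), sum(xi / v^2),
                         sum(xi / v^2), sum(1 / v^2)), 2, 2)
  vc_cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sA + sR
  h2 <- if (tot > 0) sA / tot else 0
  grad <- c(sR, -sA) / tot^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% vc_cov %*% grad)))
  if (!converged)
    warning(sprintf("EM-REML did not converge in %d iterations", max_iter),
            call. = FALSE)
  structure(list(sigma2_A = sA, sigma2_R = sR, h2 = h2, se_h2 = se_h2,
                 se_sigma2 = sqrt(pmax(0, diag(vc_cov))),
                 converged = converged, iterations = iter, loglik = loglik,
                 y = y, X = X, Z = Z, A = A),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Pedigree variance components (EM-REML)\n")
  cat(sprintf("  sigma2_A = %.4g (SE %.3g)\n  sigma2_R = %.4g (SE %.3g)\n",
              x$sigma2_A, x$se_sigma2[1], x$sigma2_R, x$se_sigma2[2]))
  cat(sprintf("  h2 = %.3f +/- %.3f  (%s, %d iterations)\n", x$h2, x$se_h2,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) {
  c(sigma2_A = object$sigma2_A, sigma2_R = object$sigma2_R, h2 = object$h2)
}

#' BLUP breeding values
#'
#' Solves Henderson's mixed-model equations at the estimated variance
#' components and returns the predicted breeding values (the random effect
#' `u`, one per row of `A`). As `sigma2_A` approaches 0 all breeding values
#' shrink to 0.
#'
#' @param fit a `reml_fit` from [reml_h2()], or a list with elements
#'   `y, X, Z, A, sigma2_A, sigma2_R`.
#' @return named numeric vector of breeding values.
#' @export
blup_breeding_values <- function(fit) {
  y <- fit$y; X <- fit$X; A <- fit$A
  Z <- if (is.null(fit$Z)) diag(nrow(A)) else fit$Z
  q <- nrow(A)
  if (fit$sigma2_A <= 1e-12 * max(fit$sigma2_R, 1)) {
    u <- rep(0, q); names(u) <- rownames(A); return(u)
  }
  lambda <- fit$sigma2_R / fit$sigma2_A
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular relationship matrix; cannot form the mixed-model ",
         "equations", call. = FALSE))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * Ainv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("singular mixed-model equations", call. = FALSE))
  u <- sol[(ncol(X) + 1):length(sol)]
  names(u) <- rownames(A)
  u
}
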