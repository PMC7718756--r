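# Genetic maps, pseudo-testcross genotype matrices, map functions and
# QTL-genotype probabilities along the map.

#' Genetic map
#'
#' Marker positions per linkage group in centimorgans, optionally with
#' physical (bp) positions for interval reporting.
#'
#' @param group vector of linkage-group identifiers.
#' @param marker unique marker names.
#' @param cM map positions, non-decreasing within each group.
#' @param bp optional physical positions.
#' @return a data frame of class `genetic_map`.
#' @export
genetic_map <- function(group, marker, cM, bp = NULL) {
  df <- data.frame(group = as.character(group), marker = as.character(marker),
                   cM = as.numeric(cM))
  if (!is.null(bp)) df$bp <- as.numeric(bp)
  if (anyDuplicated(df$marker))
    stop("marker names must be unique", call. = FALSE)
  df <- df[order(df$group, df$cM), , drop = FALSE]
  rownames(df) <- NULL
  bad <- tapply(df$cM, df$group, function(x) any(diff(x) < 0))
  if (any(unlist(bad)))
    stop("cM positions must be non-decreasing within a group", call. = FALSE)
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @export
print.genetic_map <- function(x, ...) {
  span <- tapply(x$cM, x$group, function(p) diff(range(p)))
  cat(sprintf("<genetic_map> %d markers on %d group(s), total %.2f cM\n",
              nrow(x), length(span), sum(span)))
  invisible(x)
}

#' Pseudo-testcross genotype matrix
#'
#' Individuals x markers matrix of backcross-style codes: `"A"`
#' (homozygous-like) and `"H"` (heterozygous-like), `NA` for missing. Each
#' outbred parent's heterozygous markers segregate 1:1 in the progeny, so
#' each parental map is scanned as a backcross.
#'
#' @param x character matrix with values in `{"A", "H", NA}`; rownames are
#'   individual ids, colnames marker names.
#' @return the validated matrix with class `genotype_matrix`.
#' @export
genotype_matrix <- function(x) {
  x <- as.matrix(x)
  if (!all(x %in% c("A", "H", NA)))
    stop("genotype codes must be 'A', 'H' or NA", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("individual and marker ids must be unique", call. = FALSE)
  class(x) <- c("genotype_matrix", class(x))
  x
}

#' Map distance to recombination fraction
#'
#' Haldane's map function `r = (1 - exp(-2 d / 100)) / 2` (no interference);
#' Kosambi `r = tanh(2 d / 100) / 2` available by flag.
#'
#' @param d_cM non-negative distance in centimorgans.
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
recomb_fraction <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cM < 0, na.rm = TRUE))
    stop("map distance must be non-negative", call. = FALSE)
  if (map_function == "haldane") (1 - exp(-2 * d_cM / 100)) / 2
  else tanh(2 * d_cM / 100) / 2
}

# P(genotype at position p = A | nearest informative flanking markers), for
# a two-state no-error Markov chain along the chromosome. Exact
# forward-backward result expressed in closed form; vectorized over
# positions, with NA flanking position meaning no informative marker on
# that side (gL, gR coded 1 = A, 0 = H).
.prob_A_between <- function(p, pL, gL, pR, gR, map_function) {
  rL <- recomb_fraction(ifelse(is.na(pL), 0, p - pL), map_function)
  rR <- recomb_fraction(ifelse(is.na(pR), 0, pR - p), map_function)
  sL <- ifelse(gL == 1, 1 - rL, rL)      # P(gL -> A over left gap)
  sR <- ifelse(gR == 1, 1 - rR, rR)      # P(A -> gR over right gap)
  out <- sL * sR / (sL * sR + (1 - sL) * (1 - sR))
  out <- ifelse(is.na(pL) & is.na(pR), 0.5,
         ifelse(is.na(pR), sL,
         ifelse(is.na(pL), sR, out)))
  out
}

#' QTL genotype probabilities along the map
#'
#' Computes `P(QTL genotype = A | marker data)` for every individual at a
#' grid of positions (every `step_cM`, plus all marker positions) along each
#' linkage group, under a two-genotype (pseudo-testcross) no-error Markov
#' model with the chosen map function. At a typed marker the probability is
#' 0 or 1; a fully missing individual gets the 0.5 prior everywhere. This is
#' the exact conditional expectation that Haley-Knott regression requires
#' (a deterministic replacement for multiple imputation).
#'
#' @param map a [genetic_map()].
#' @param genos a [genotype_matrix()] whose columns are (a subset of) the
#'   map's markers.
#' @param step_cM grid step in centimorgans (default 1).
#' @param map_function see [recomb_fraction()].
#' @return an object of class `qtl_probs`: per group a list with `pos`
#'   (grid positions) and `probA` (individuals x positions matrix).
#' @export
genotype_probs <- function(map, genos, step_cM = 1,
                           map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  stopifnot(inherits(map, "genetic_map"))
  missing_markers <- setdiff(colnames(genos), map$marker)
  if (length(missing_markers))
    stop("markers absent from the map: ",
         paste(utils::head(missing_markers, 5), collapse = ", "),
         call. = FALSE)
  n <- nrow(genos)
  groups <- unique(map$group)
  all_missing <- apply(genos, 1, function(x) all(is.na(x)))
  if (any(all_missing))
    warning(sum(all_missing), " individual(s) with no genotype data; ",
            "uniform probabilities used", call. = FALSE)
  res <- lapply(groups, function(gr) {
    sub <- map[map$group == gr & map$marker %in% colnames(genos), ,
               drop = FALSE]
    if (!nrow(sub)) return(NULL)
    mpos <- sub$cM
    grid <- sort(unique(c(mpos, seq(min(mpos), max(mpos), by = step_cM))))
    G <- matrix(NA_real_, n, length(mpos))
    gm <- genos[, sub$marker, drop = FALSE]
    G[gm == "A"] <- 1
    G[gm == "H"] <- 0
    probA <- matrix(0.5, n, length(grid),
                    dimnames = list(rownames(genos), NULL))
    for (i in seq_len(n)) {
      obs <- which(!is.na(G[i, ]))
      if (!length(obs)) next
      po <- mpos[obs]
      go <- G[i, obs]
      li <- findInterval(grid, po)           # index of nearest obs <= p
      iL <- ifelse(li >= 1L, li, NA_integer_)
      iR <- ifelse(li < length(po), li + 1L, NA_integer_)
      pL <- po[iL]; gL <- go[iL]
      pR <- po[iR]; gR <- go[iR]
      pr <- .prob_A_between(grid, pL, gL, pR, gR, map_function)
      at_marker <- !is.na(pL) & pL == grid   # typed marker: no uncertainty
      pr[at_marker] <- gL[at_marker]
      probA[i, ] <- pr
    }
    list(pos = grid, probA = probA)
  })
  names(res) <- groups
  res <- res[!vapply(res, is.null, logical(1))]
  structure(list(groups = res, step_cM = step_cM,
                 map_function = map_function, map = map),
            class = "qtl_probs")
}

#' @export
print.qtl_probs <- function(x, ...) {
  np <- sum(vapply(x$groups, function(g) length(g$pos), integer(1)))
  cat(sprintf(
    "<qtl_probs> %d individuals, %d group(s), %d grid positions (step %g cM, %s)\n",
    nrow(x$groups[[1]]$probA), length(x$groups), np, x$step_cM,
    x$map_function))
  invisible(x)
}
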