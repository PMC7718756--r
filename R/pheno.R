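# Per-tree aggregation, ANOVA of the multi-year color phenotypes,
# adjusted genotype means and trait correlations.

#' Aggregate kernel measurements per tree and year
#'
#' The field protocol measures 10 kernels per tree; the tree-level phenotype
#' is the arithmetic mean of L*, a*, b* and of the ordinal DFA class.
#'
#' @param kernels data frame of kernel measurements containing columns
#'   `L, a, b, dfa_class` plus the grouping columns.
#' @param tree_id,year vectors (recycled against `kernels` rows) identifying
#'   tree and harvest year of each kernel.
#' @return data frame with one row per tree-year: means of the four traits
#'   and the kernel count `n`.
#' @export
aggregate_tree <- function(kernels, tree_id, year) {
  if (!nrow(kernels)) stop("no kernel measurements supplied", call. = FALSE)
  grp <- data.frame(tree_id = tree_id, year = year)
  agg <- stats::aggregate(kernels[, c("L", "a", "b", "dfa_class")],
                          by = grp, FUN = mean)
  n <- stats::aggregate(list(n = kernels$L), by = grp, FUN = length)
  out <- merge(agg, n, by = c("tree_id", "year"))
  names(out)[names(out) == "dfa_class"] <- "dfa"
  out[order(out$tree_id, out$year), , drop = FALSE]
}

.pheno_validate <- function(table, trait, need = c("tree_id", "year")) {
  stopifnot(is.data.frame(table))
  miss <- setdiff(c(need, "trait", "value"), names(table))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- table[table$trait == trait, , drop = FALSE]
  if (!nrow(df)) stop(sprintf("no records for trait '%s'", trait),
                      call. = FALSE)
  df
}

#' Multi-year ANOVA of a color trait
#'
#' Fits the linear model `value ~ age + family + family:genotype + year +
#' family:year` — family, genotype nested within family, harvest year, the
#' family-by-year interaction and tree age as a covariate — and returns the
#' Type-II analysis-of-variance table (suited to the unbalanced family
#' structure of a breeding program).
#'
#' @param table long-format phenotype data frame with columns
#'   `tree_id, family, year, age, trait, value`.
#' @param trait which trait to analyse (e.g. `"L"`, `"dfa"`).
#' @return a list of class `color_anova`: `anova_table` (factor, df, SS, F,
#'   p), `sigma2_res` (residual variance), and the underlying `lm` fit.
#' @export
fit_color_anova <- function(table, trait) {
  df <- .pheno_validate(table, trait, need = c("tree_id", "family", "year",
                                               "age"))
  df$family <- factor(df$family)
  df$genotype <- factor(df$tree_id)
  df$year <- factor(df$year)
  for (f in c("family", "year"))
    if (nlevels(df[[f]]) < 2)
      stop(sprintf("factor '%s' needs at least 2 levels", f), call. = FALSE)
  fit <- stats::lm(value ~ age + family + family:genotype + year +
                     family:year, data = df)
  if (stats::sd(df$value) == 0) {
    tab <- data.frame(factor = "residual", df = fit$df.residual,
                      sum_sq = 0, f_value = NA_real_, p_value = NA_real_)
    return(structure(list(anova_table = tab, sigma2_res = 0, fit = fit),
                     class = "color_anova"))
  }
  a2 <- tryCatch(car::Anova(fit, type = 2, singular.ok = TRUE),
                 error = function(e) {
                   warning("rank-deficient design; falling back to ",
                           "sequential (Type I) sums of squares",
                           call. = FALSE)
                   stats::anova(fit)
                 })
  tab <- data.frame(factor = rownames(a2),
                    sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    f_value = if ("F value" %in% names(a2)) a2[["F value"]] else NA_real_,
                    p_value = if ("Pr(>F)" %in% names(a2)) a2[["Pr(>F)"]] else NA_real_)
  sigma2 <- tab$sum_sq[tab$factor == "Residuals"] /
    tab$df[tab$factor == "Residuals"]
  if (!length(sigma2)) sigma2 <- summary(fit)$sigma^2
  structure(list(anova_table = tab, sigma2_res = as.numeric(sigma2),
                 fit = fit), class = "color_anova")
}

#' @export
print.color_anova <- function(x, ...) {
  cat("Multi-year color trait ANOVA (Type II SS)\n")
  print(x$anova_table, row.names = FALSE, digits = 4)
  cat(sprintf("residual variance: %.4g\n", x$sigma2_res))
  invisible(x)
}

#' Adjusted genotype means over years
#'
#' Least-squares means per genotype from the two-way model
#' `value ~ genotype * year`, averaging over year levels with equal weights
#' (the reference-grid convention). On balanced data this equals the simple
#' genotype mean. Genotypes with empty year cells are averaged over their
#' estimable cells only and flagged.
#'
#' @param table long-format phenotype data frame with columns
#'   `tree_id, year, trait, value`.
#' @param trait which trait to analyse.
#' @return data frame `genotype, lsmean, se, incomplete` (logical flag for
#'   genotypes missing one or more years).
#' @export
adjusted_means <- function(table, trait) {
  df <- .pheno_validate(table, trait)
  df$genotype <- factor(df$tree_id)
  df$year <- factor(df$year)
  if (nlevels(df$year) == 1L) {
    agg <- stats::aggregate(value ~ genotype, data = df, FUN = mean)
    n <- stats::aggregate(value ~ genotype, data = df, FUN = length)
    s2 <- stats::var(df$value)
    return(data.frame(genotype = as.character(agg$genotype),
                      lsmean = agg$value,
                      se = sqrt(s2 / n$value),
                      incomplete = FALSE))
  }
  fit <- stats::lm(value ~ genotype * year, data = df)
  em <- suppressMessages(
    as.data.frame(emmeans::emmeans(fit, "genotype"))
  )
  out <- data.frame(genotype = as.character(em$genotype),
                    lsmean = em$emmean, se = em$SE,
                    incomplete = FALSE)
  if (anyNA(out$lsmean)) {
    # non-estimable genotypes: average over the years actually observed
    cell <- stats::aggregate(value ~ genotype + year, data = df, FUN = mean)
    for (g in out$genotype[is.na(out$lsmean)]) {
      cm <- cell$value[cell$genotype == g]
      i <- out$genotype == g
      out$lsmean[i] <- mean(cm)
      out$incomplete[i] <- TRUE
    }
  }
  out
}

#' Correlations between trait adjusted means
#'
#' Pearson correlation matrix across genotypes of the adjusted means of the
#' four color traits (L*, a*, b*, DFA). Zero-variance traits yield `NA`
#' entries with a warning.
#'
#' @param means data frame with one row per genotype and one column per
#'   trait (non-numeric columns such as `genotype` are ignored).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(means) {
  num <- means[, vapply(means, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3) stop("need at least 3 genotypes", call. = FALSE)
  sds <- vapply(num, stats::sd, numeric(1))
  if (any(sds == 0))
    warning("zero-variance trait(s): ",
            paste(names(num)[sds == 0], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  suppressWarnings(stats::cor(as.matrix(num)))
}
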