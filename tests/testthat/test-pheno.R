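# Tree-level aggregation, multi-year ANOVA, adjusted means and trait
# correlations.

test_that("tree aggregation takes arithmetic means per tree-year", {
  k <- data.frame(L = c(rep(60, 10), 50), a = 5, b = 20,
                  dfa_class = c(1, 1, 2, 2, 2, 2, 2, 2, 3, 3, 4))
  agg <- aggregate_tree(k, tree_id = c(rep("t1", 10), "t2"),
                        year = 2016)
  expect_equal(agg$dfa[agg$tree_id == "t1"], 2.0)
  expect_equal(agg$L[agg$tree_id == "t1"], 60)
  expect_equal(agg$n[agg$tree_id == "t1"], 10L)
  # a single kernel aggregates to itself
  expect_equal(agg$dfa[agg$tree_id == "t2"], 4)
})

# Balanced two-family design: 2 families x 2 genotypes each x 2 years x 2
# reps, with a mirrored age covariate orthogonal to every factor.
balanced_design <- function() {
  d <- expand.grid(genotype = c("g1", "g2", "g3", "g4"),
                   year = c("2016", "2017"), rep = 1:2)
  d$family <- ifelse(d$genotype %in% c("g1", "g2"), "f1", "f2")
  d$age <- ifelse(d$rep == 1, -1, 1)
  d
}

test_that("a pure additive year shift carries its closed-form SS", {
  d <- balanced_design()
  d$value <- 50 + 5 * (d$year == "2017")
  tab <- make_pheno_table(d$value, d$genotype, d$family, d$year, d$age)
  # a noiseless response makes the F machinery complain; the SS are exact
  fit <- suppressWarnings(fit_color_anova(tab, "L"))
  at <- fit$anova_table
  # balanced 2-level factor, shift delta: SS = N * (delta/2)^2
  expect_equal(at$sum_sq[at$factor == "year"], nrow(d) * (5 / 2)^2,
               tolerance = 1e-8)
  expect_equal(fit$sigma2_res, 0, tolerance = 1e-12)
})

test_that("type-II sums of squares add to the total on orthogonal designs", {
  d <- balanced_design()
  set.seed(11)
  d$value <- 50 + 3 * (d$family == "f2") + 2 * (d$year == "2017") +
    c(g1 = 0, g2 = 1, g3 = -1, g4 = 2)[as.character(d$genotype)] +
    0.5 * d$age + rnorm(nrow(d), 0, 0.3)
  tab <- make_pheno_table(d$value, d$genotype, d$family, d$year, d$age)
  fit <- fit_color_anova(tab, "L")
  total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(fit$anova_table$sum_sq), total, tolerance = 1e-6)
})

test_that("the family test is calibrated under a null family effect", {
  d <- balanced_design()
  reject <- 0
  n_rep <- 200
  set.seed(99)
  for (r in seq_len(n_rep)) {
    d$value <- 50 + 2 * (d$year == "2017") + rnorm(nrow(d))
    tab <- make_pheno_table(d$value, d$genotype, d$family, d$year, d$age)
    fit <- fit_color_anova(tab, "L")
    p <- fit$anova_table$p_value[fit$anova_table$factor == "family"]
    if (p < 0.05) reject <- reject + 1
  }
  expect_gt(reject / n_rep, 0.01)
  expect_lt(reject / n_rep, 0.11)
})

test_that("constant response yields zero residual variance", {
  d <- balanced_design()
  tab <- make_pheno_table(rep(7, nrow(d)), d$genotype, d$family, d$year,
                          d$age)
  fit <- fit_color_anova(tab, "L")
  expect_equal(fit$sigma2_res, 0)
})

test_that("adjusted means equal group means on balanced data", {
  d <- expand.grid(genotype = c("A", "B", "C"), year = c("y1", "y2"),
                   rep = 1:3)
  set.seed(2)
  d$value <- 50 + 2 * (d$genotype == "B") + 3 * (d$year == "y2") + rnorm(nrow(d))
  tab <- make_pheno_table(d$value, d$genotype, "f", d$year)
  am <- adjusted_means(tab, "L")
  raw <- tapply(d$value, d$genotype, mean)
  expect_equal(am$lsmean[match(names(raw), am$genotype)], as.numeric(raw),
               tolerance = 1e-10)
})

test_that("adjusted means average year cell means in unbalanced data", {
  # genotype A: 9 obs at 60 in year 1, 1 obs at 70 in year 2; null year
  # effects -> lsmean is the equal-weight cell-mean average 65
  d <- data.frame(genotype = c(rep("A", 10), rep("B", 8)),
                  year = c(rep("y1", 9), "y2", rep(c("y1", "y2"), 4)),
                  value = c(rep(60, 9), 70, rep(64, 8)))
  tab <- make_pheno_table(d$value, d$genotype, "f", d$year)
  am <- suppressWarnings(adjusted_means(tab, "L"))  # cells fit exactly
  expect_equal(am$lsmean[am$genotype == "A"], 65, tolerance = 1e-10)
  # hand oracle via the interaction-model normal equations = cell means
  cellA <- tapply(d$value[d$genotype == "A"], d$year[d$genotype == "A"],
                  mean)
  expect_equal(am$lsmean[am$genotype == "A"], mean(cellA),
               tolerance = 1e-10)
})

test_that("a genotype observed in one year only is flagged, not dropped", {
  d <- data.frame(genotype = c(rep("A", 4), rep("B", 4), rep("C", 2)),
                  year = c(rep(c("y1", "y2"), 4), "y1", "y1"),
                  value = c(60, 62, 58, 61, 55, 57, 54, 56, 66, 67))
  tab <- make_pheno_table(d$value, d$genotype, "f", d$year)
  am <- adjusted_means(tab, "L")
  expect_true(am$incomplete[am$genotype == "C"])
  expect_equal(am$lsmean[am$genotype == "C"], 66.5)
})

test_that("trait correlations are exact for linear dependence", {
  set.seed(8)
  L <- rnorm(50, 60, 5)
  m <- data.frame(genotype = paste0("g", 1:50), L = L, b = 2 * L + 1,
                  a = rnorm(50))
  cm <- trait_correlations(m)
  expect_equal(cm["L", "b"], 1, tolerance = 1e-12)
  expect_equal(diag(cm), c(L = 1, b = 1, a = 1))
  expect_true(isSymmetric(cm))
  # independent traits at n = 500 stay near zero
  m2 <- data.frame(x = rnorm(500), y = rnorm(500), z = rnorm(500))
  expect_lt(max(abs(trait_correlations(m2)[upper.tri(diag(3))])), 0.12)
  # zero-variance trait flagged
  m3 <- data.frame(x = rnorm(10), flat = rep(1, 10))
  expect_warning(cz <- trait_correlations(m3), "zero-variance")
  expect_true(is.na(cz["x", "flat"]))
})
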