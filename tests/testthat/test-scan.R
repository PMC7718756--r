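# Haley-Knott scanning, permutation thresholds, p-values, Bayes intervals,
# multi-QTL fits and refinement.

scan_fixture <- function(seed = 1, n = 120, effect = 1) {
  map <- simulate_genetic_map(n_groups = 2, markers_per_group = 15,
                              length_cM = 50, seed = seed)
  sim <- simulate_cross(map, n_progeny = n,
                        qtl = if (effect != 0)
                          data.frame(group = "LG1", pos = 25,
                                     effect = effect) else NULL,
                        seed = seed + 1)
  probs <- genotype_probs(map, sim$genotypes)
  list(map = map, sim = sim, probs = probs)
}

test_that("scan LOD equals the brute-force regression oracle at markers", {
  fx <- scan_fixture(seed = 3)
  scan <- scanone_hk(fx$probs, fx$sim$phenotype)
  for (g in names(fx$probs$groups)) {
    sub <- fx$map[fx$map$group == g, ]
    probA <- fx$probs$groups[[g]]$probA
    grid <- fx$probs$groups[[g]]$pos
    for (mk in sample(sub$marker, 4)) {
      pos <- sub$cM[sub$marker == mk]
      x <- (unclass(fx$sim$genotypes)[, mk] == "A") * 1
      expected <- oracle_marker_lod(fx$sim$phenotype, x)
      got <- scan$lod[scan$group == g & scan$pos == pos]
      expect_equal(got, expected, tolerance = 1e-10)
    }
  }
})

test_that("near-deterministic marker effects give the closed-form LOD", {
  map <- genetic_map(rep("g", 2), c("m1", "m2"), c(0, 40))
  set.seed(9)
  gt <- sample(0:1, 150, replace = TRUE)
  codes <- cbind(m1 = ifelse(gt == 1, "A", "H"),
                 m2 = sample(c("A", "H"), 150, replace = TRUE))
  rownames(codes) <- paste0("i", 1:150)
  y <- gt * 10 + rnorm(150, 0, 0.1)
  probs <- genotype_probs(map, genotype_matrix(codes))
  scan <- scanone_hk(probs, y)
  expect_equal(scan$lod[scan$pos == 0][1], oracle_marker_lod(y, gt),
               tolerance = 1e-10)
})

test_that("duplicating every observation exactly doubles the LOD", {
  fx <- scan_fixture(seed = 5, n = 60)
  scan1 <- scanone_hk(fx$probs, fx$sim$phenotype)
  dup_probs <- fx$probs
  for (g in names(dup_probs$groups)) {
    m <- dup_probs$groups[[g]]$probA
    dup_probs$groups[[g]]$probA <- rbind(m, m)
  }
  scan2 <- scanone_hk(dup_probs, rep(fx$sim$phenotype, 2))
  expect_equal(scan2$lod, 2 * scan1$lod, tolerance = 1e-9)
})

test_that("degenerate phenotypes are rejected", {
  fx <- scan_fixture(seed = 7, n = 40)
  expect_error(scanone_hk(fx$probs, rep(1, 40)), "constant")
})

test_that("permutation thresholds are seeded and hit quantile edges", {
  fx <- scan_fixture(seed = 11, n = 80, effect = 0)
  p1 <- permutation_threshold(fx$probs, fx$sim$phenotype, n_perm = 120,
                              seed = 42)
  p2 <- permutation_threshold(fx$probs, fx$sim$phenotype, n_perm = 120,
                              seed = 42)
  expect_identical(p1$threshold, p2$threshold)
  expect_identical(p1$max_lods, p2$max_lods)
  p3 <- permutation_threshold(fx$probs, fx$sim$phenotype, n_perm = 120,
                              alpha = 1, seed = 42)
  expect_equal(p3$threshold, min(p1$max_lods))
  expect_error(permutation_threshold(fx$probs, fx$sim$phenotype,
                                     n_perm = 50), "at least 100")
})

test_that("genome-wide p-values follow the plus-one empirical rule", {
  sample <- c(1, 2, 3, 4, 5)
  expect_equal(lod_to_pvalue(10, sample), 1 / 6)
  expect_equal(lod_to_pvalue(0, sample), 1)
  expect_equal(lod_to_pvalue(3, sample), 4 / 6)   # ties count as >=
  perm <- structure(list(max_lods = rep(1, 1000)), class = "qtl_perm")
  expect_equal(lod_to_pvalue(5, perm), 1 / 1001)
})

test_that("Bayes intervals collapse on spikes and widen on flat profiles", {
  grid <- data.frame(group = "g", pos = 0:10, lod = 0)
  spike <- grid; spike$lod[6] <- 20
  bi <- bayes_interval(spike, "g")
  expect_equal(c(bi$low_cM, bi$high_cM, bi$peak_cM), c(5, 5, 5))
  flat <- grid
  bf <- bayes_interval(flat, "g")
  expect_equal(c(bf$low_cM, bf$high_cM), c(0, 10))
})

test_that("Bayes interval matches enumeration on triangular profiles", {
  lod <- c(0, 0.5, 1, 1.5, 2, 2.5, 2, 1.5, 1, 0.5, 0)
  tri <- data.frame(group = "g", pos = seq(0, 50, by = 5), lod = lod)
  bi <- bayes_interval(tri, "g", coverage = 0.95)
  oracle <- oracle_bayes_window(lod, 0.95)
  expect_equal(bi$low_cM, tri$pos[oracle["i"]])
  expect_equal(bi$high_cM, tri$pos[oracle["j"]])
  expect_gte(bi$mass, 0.95)
  # asymmetric profile too
  lod2 <- c(0.1, 3, 2.8, 1, 0.4, 0.2, 0.1, 0.05)
  tri2 <- data.frame(group = "g", pos = seq_along(lod2), lod = lod2)
  bi2 <- bayes_interval(tri2, "g", coverage = 0.9)
  o2 <- oracle_bayes_window(lod2, 0.9)
  expect_equal(c(bi2$low_cM, bi2$high_cM),
               c(tri2$pos[o2["i"]], tri2$pos[o2["j"]]))
})

test_that("physical positions interpolate from the map", {
  map <- genetic_map(rep("g", 3), paste0("m", 1:3), c(0, 10, 20),
                     bp = c(0, 1e6, 2e6))
  grid <- data.frame(group = "g", pos = 0:20, lod = 0)
  grid$lod[grid$pos == 15] <- 20
  bi <- bayes_interval(grid, "g", map = map)
  expect_equal(bi$peak_bp, 1.5e6)
})

test_that("a single-QTL fit reduces to the scan at that position", {
  fx <- scan_fixture(seed = 13)
  scan <- scanone_hk(fx$probs, fx$sim$phenotype)
  peak <- summary(scan)[1, ]
  fit <- fit_multi_qtl(fx$probs, fx$sim$phenotype,
                       data.frame(group = peak$group, pos = peak$pos))
  expect_equal(fit$joint$lod, peak$lod, tolerance = 1e-9)
  expect_equal(fit$per_qtl$lod, peak$lod, tolerance = 1e-9)
})

test_that("two planted additive QTL recover their variance shares", {
  map <- simulate_genetic_map(n_groups = 2, markers_per_group = 25,
                              length_cM = 60, seed = 19)
  qtl <- data.frame(group = c("LG1", "LG2"), pos = c(30, 30),
                    effect = c(1, 1))
  r2_1 <- r2_2 <- numeric(10)
  for (r in 1:10) {
    sim <- simulate_cross(map, n_progeny = 300, qtl = qtl, seed = 100 + r)
    probs <- genotype_probs(map, sim$genotypes)
    fit <- fit_multi_qtl(probs, sim$phenotype, qtl[, c("group", "pos")])
    r2_1[r] <- fit$per_qtl$r2[1]; r2_2[r] <- fit$per_qtl$r2[2]
  }
  # each QTL explains var 0.25/(0.25+0.25+1) ~ 0.167 of the phenotype
  expect_equal(mean(r2_1), 1 / 6, tolerance = 0.25)
  expect_equal(mean(r2_2), 1 / 6, tolerance = 0.25)
  # a pure-noise joint fit explains almost nothing
  sim0 <- simulate_cross(map, n_progeny = 300, seed = 7)
  probs0 <- genotype_probs(map, sim0$genotypes)
  fit0 <- fit_multi_qtl(probs0, sim0$phenotype, qtl[, c("group", "pos")])
  expect_lt(fit0$joint$r2, 0.08)
})

test_that("refinement is monotone and finds a displaced QTL", {
  fx <- scan_fixture(seed = 23, n = 200, effect = 1)
  scan <- scanone_hk(fx$probs, fx$sim$phenotype)
  peak <- summary(scan)[summary(scan)$group == "LG1", ]
  # already-optimal start: unchanged
  at_peak <- refine_positions(fx$probs, fx$sim$phenotype,
                              data.frame(group = "LG1", pos = peak$pos))
  expect_equal(at_peak$pos, peak$pos)
  # displaced start moves to within 2 cM of the truth (planted at 25)
  displaced <- data.frame(group = "LG1", pos = peak$pos + 5)
  start_lod <- attr(refine_positions(fx$probs, fx$sim$phenotype, displaced,
                                     max_iter = 0), "joint_lod")
  refined <- refine_positions(fx$probs, fx$sim$phenotype, displaced)
  expect_lte(abs(refined$pos - 25), 2)
  expect_gte(attr(refined, "joint_lod"), start_lod)
})

test_that("QTL positions under 1 cM apart raise a collinearity warning", {
  fx <- scan_fixture(seed = 29, n = 60)
  pos <- data.frame(group = c("LG1", "LG1"), pos = c(20, 20.4))
  expect_warning(fit_multi_qtl(fx$probs, fx$sim$phenotype, pos),
                 "collinear")
})
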