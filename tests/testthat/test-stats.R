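test_that("Mantel correlation hits the permutation floor on perfect association", {
  set.seed(5)
  pts <- matrix(stats::rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  dm <- as.matrix(stats::dist(pts))
  m <- mantel(dm, 2 * dm, n_perm = 199, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 200)

  # r agrees with the independent vegan implementation
  set.seed(6)
  pts2 <- matrix(stats::rnorm(20), 10, 2)
  dm2 <- as.matrix(stats::dist(pts2))
  dimnames(dm2) <- dimnames(dm)
  expect_equal(mantel(dm, dm2, n_perm = 99, seed = 1)$r,
               unname(vegan::mantel(stats::as.dist(dm), stats::as.dist(dm2),
                                    permutations = 0)$statistic))

  # invariant to simultaneous relabelling / reordering
  ord <- sample(rownames(dm))
  expect_equal(mantel(dm[ord, ord], dm2, n_perm = 99, seed = 2)$r,
               mantel(dm, dm2, n_perm = 99, seed = 2)$r)

  cm <- matrix(1, 10, 10, dimnames = dimnames(dm)); diag(cm) <- 0
  expect_error(mantel(dm, cm), "constant")
  dm3 <- dm2
  rownames(dm3) <- colnames(dm3) <- paste0("x", 1:10)
  expect_error(mantel(dm, dm3), "different samples")
})

test_that("the rank-sum screen is exact under complete separation", {
  f <- rbind(f1 = c(1:5, 11:15))
  colnames(f) <- paste0("s", 1:10)
  g <- c(rep("trt", 5), rep("ref", 5))
  r <- wilcoxon_screen(f, g, reference_group = "ref", alternative = "decrease")
  expect_equal(r$p, 1 / choose(10, 5))
  expect_identical(r$direction, "decreased")

  # identical groups: maximal p, not significant
  f2 <- rbind(f1 = rep(c(1, 2, 3, 4, 5), 2))
  colnames(f2) <- paste0("s", 1:10)
  r2 <- wilcoxon_screen(f2, g, reference_group = "ref",
                        alternative = "two_sided")
  expect_gt(r2$p, 0.5)
  expect_false(r2$significant)

  # constant feature flagged with p = 1
  f3 <- rbind(f1 = rep(7, 10))
  colnames(f3) <- paste0("s", 1:10)
  r3 <- wilcoxon_screen(f3, g, reference_group = "ref")
  expect_true(r3$constant)
  expect_equal(r3$p, 1)

  expect_error(wilcoxon_screen(f, g, reference_group = "nope"), "not present")
})

test_that("BH adjustment is order-invariant and monotone", {
  ft <- simulate_feature_table(60, rep(c("ref", "trt"), each = 10),
                               effect_size = 1.5, seed = 7)
  sc <- wilcoxon_screen(ft$features, ft$groups, reference_group = "ref")
  expect_true(all(sc$p_adj >= sc$p - 1e-12))
  ord <- order(sc$p)
  expect_true(all(diff(sc$p_adj[ord]) >= -1e-12))

  shuf <- sample(nrow(ft$features))
  sc2 <- wilcoxon_screen(ft$features[shuf, ], ft$groups, reference_group = "ref")
  expect_equal(sc2$p_adj[match(sc$feature, sc2$feature)], sc$p_adj)
})

test_that("ANOVA with Tukey letters behaves under null and strong separation", {
  # strong separation: disjoint letters
  set.seed(8)
  v <- c(stats::rnorm(6), stats::rnorm(6) + 10)
  g <- rep(c("A", "B"), each = 6)
  at <- anova_tukey(v, g)
  expect_false(at$letters["A"] == at$letters["B"])
  expect_lt(at$p, 0.01)

  # null: all groups share a letter in >= 90% of runs
  shared <- vapply(1:100, function(s) {
    set.seed(400 + s)
    vv <- stats::rnorm(15)
    gg <- rep(c("A", "B", "C"), each = 5)
    lt <- anova_tukey(vv, gg)$letters
    length(Reduce(intersect, strsplit(lt, ""))) > 0
  }, logical(1))
  expect_gte(mean(shared), 0.9)

  # balanced null: E[F] is close to 1
  fs <- vapply(1:500, function(s) {
    set.seed(900 + s)
    anova_tukey(stats::rnorm(20), rep(c("A", "B"), each = 10))$f
  }, numeric(1))
  expect_true(mean(fs) > 0.8 && mean(fs) < 1.2)

  expect_error(anova_tukey(rep(c(1, 2), each = 3), rep(c("A", "B"), each = 3)),
               "zero within-group variance")
})

test_that("z-scoring centers and scales per feature", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(9)
  m <- matrix(stats::rnorm(40, sd = 4), 8, 5,
              dimnames = list(paste0("e", 1:8), paste0("s", 1:5)))
  z <- zscore(m)
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, stats::sd) - 1)), 1e-12)
  expect_error(zscore(rep(2, 5)), "zero variance")
})

test_that("RPKM matches its formula and scaling law", {
  gt <- gene_table(matrix(10L, 1, 1, dimnames = list("g1", "s1")), 1000, 1e6)
  expect_equal(unname(rpkm(gt)[1, 1]), 10)

  counts <- matrix(c(0L, 40L, 12L, 8L), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  gt2 <- gene_table(counts, c(500, 2000), c(1e6, 2e6))
  rk <- rpkm(gt2)
  expect_equal(rk["g1", "s1"], 0)
  gt3 <- gene_table(counts, c(500, 2000), 2 * c(1e6, 2e6))
  expect_equal(rpkm(gt3), rk / 2)

  zero_counts <- matrix(0L, 2, 2, dimnames = dimnames(counts))
  gt0 <- gene_table(zero_counts, c(500, 2000), c(0, 2e6))
  expect_error(rpkm(gt0), "zero total mapped reads")
})

test_that("the permutation slope test is exact on perfect fits", {
  st <- permutation_slope_test(1:10, 3 * (1:10), n_perm = 199, seed = 2)
  expect_equal(st$slope, 3)
  expect_equal(st$p, 1 / 200)
  expect_gte(st$p, 1 / (st$n_perm + 1))
  expect_error(permutation_slope_test(rep(1, 5), stats::rnorm(5)), "constant x")
  expect_error(permutation_slope_test(1:3, 1:3), ">= 4")
})
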