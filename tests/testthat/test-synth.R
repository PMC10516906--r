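test_that("simulated trees are valid, labelled and deterministic", {
  tr <- simulate_tree(8, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(unique(tr$tip.label), 8)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(8, seed = 1)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(8, seed = 2)),
                         ape::write.tree(tr)))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("community generator conserves depth and respects the seed", {
  tree <- simulate_tree(60, seed = 4)
  sc <- assembly_scenario("neutral", n_taxa = 60, n_samples = 10,
                          depth = 2000, seed = 7)
  tab <- simulate_communities(tree, sc)
  expect_true(all(colSums(tab) == 2000))
  expect_identical(simulate_communities(tree, sc), tab)
  expect_error(assembly_scenario(depth = 0), ">= 100")
  expect_error(assembly_scenario(n_taxa = 3), ">= 4")
})

test_that("a vanishing filter degenerates to the neutral regime", {
  tree <- simulate_tree(40, seed = 9)
  # same scenario seed => same metacommunity; huge sigma => flat filter
  neutral <- assembly_scenario("neutral", n_taxa = 40, n_samples = 8,
                               depth = 5000, sample_noise_sdlog = 0, seed = 3)
  flat <- assembly_scenario("homogeneous_selection", n_taxa = 40,
                            n_samples = 8, depth = 5000,
                            selection_strength = 1e6,
                            sample_noise_sdlog = 0, seed = 3)
  mean_rel <- function(x) rowMeans(sweep(x, 2, colSums(x), "/"))
  p_n <- mean_rel(simulate_communities(tree, neutral))
  p_f <- mean_rel(simulate_communities(tree, flat))
  expect_gt(stats::cor(p_n, p_f), 0.99)
})

test_that("an underflowing filter errors with advice", {
  tree <- simulate_tree(20, seed = 2)
  sc <- assembly_scenario("homogeneous_selection", n_taxa = 20, n_samples = 4,
                          depth = 500, selection_strength = 1e-12, seed = 5)
  expect_error(simulate_communities(tree, sc), "selection_strength")
})

test_that("variable selection separates sample blocks compositionally", {
  tree <- simulate_tree(80, seed = 6)
  sc <- assembly_scenario("variable_selection", n_taxa = 80, n_samples = 10,
                          depth = 2000, selection_strength = 0.3, seed = 8)
  tab <- simulate_communities(tree, sc)
  bc <- bray_curtis(tab)
  blocks <- rep(1:2, each = 5)
  same <- outer(blocks, blocks, "==")
  diag(same) <- NA
  expect_gt(stats::median(bc[!same & upper.tri(bc)], na.rm = TRUE),
            stats::median(bc[same & upper.tri(bc)], na.rm = TRUE))
})

test_that("planted co-occurrence modules show elevated within-module correlation", {
  sc <- network_scenario(n_taxa = 20, n_modules = 2, rho = 0.9,
                         n_samples = 40, seed = 5)
  tab <- simulate_cooccurrence(sc)
  expect_identical(simulate_cooccurrence(sc), tab)
  mods <- attr(tab, "modules")
  r <- stats::cor(t(log10(tab + 1)))
  same <- outer(mods, mods, "==") & upper.tri(r)
  diff <- outer(mods, mods, "!=") & upper.tri(r)
  expect_gt(mean(abs(r[same])), mean(abs(r[diff])))
  expect_error(simulate_cooccurrence(network_scenario(n_samples = 5)),
               ">= 10 samples")
})

test_that("rho = 0 leaves within- and between-module correlation indistinguishable", {
  gaps <- vapply(1:20, function(s) {
    tab <- simulate_cooccurrence(network_scenario(n_taxa = 20, n_modules = 2,
                                                  rho = 0, n_samples = 40,
                                                  seed = s))
    mods <- attr(tab, "modules")
    r <- stats::cor(t(log10(tab + 1)))
    same <- outer(mods, mods, "==") & upper.tri(r)
    diff <- outer(mods, mods, "!=") & upper.tri(r)
    mean(abs(r[same])) - mean(abs(r[diff]))
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 3 * stats::sd(gaps) / sqrt(length(gaps)))
})

test_that("feature-table generator returns the planted truth", {
  g <- rep(c("ref", "trt"), each = 10)
  ft <- simulate_feature_table(100, g, effect_size = 2, prop_shifted = 0.2,
                               seed = 4)
  expect_length(ft$truth, 20)
  expect_identical(simulate_feature_table(100, g, effect_size = 2,
                                          prop_shifted = 0.2, seed = 4)$features,
                   ft$features)
  # shifted features are lower in the treatment group
  trt <- ft$groups == "trt"
  med_diff <- apply(ft$features[ft$truth, trt], 1, stats::median) -
    apply(ft$features[ft$truth, !trt], 1, stats::median)
  expect_true(mean(med_diff < 0) > 0.9)

  expect_length(simulate_feature_table(50, g, effect_size = 0, seed = 1)$truth, 0)
  expect_error(simulate_feature_table(50, g, effect_size = -1), ">= 0")
  expect_error(simulate_feature_table(50, rep("a", 6), effect_size = 1),
               ">= 2 groups")
})
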