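test_that("betaMNTD reproduces hand-computed cases", {
  tr <- toy_tree()

  # identical communities: every taxon finds itself in the other sample
  same <- cbind(k = c(A = 2L, B = 1L, C = 1L), m = c(A = 2L, B = 1L, C = 1L))
  expect_equal(beta_mntd(same, tr, c("k", "m")), 0)

  # k = {A}, m = {B}: d(A,B) = 2 both ways
  ab <- cbind(k = c(A = 1L, B = 0L, C = 0L), m = c(A = 0L, B = 1L, C = 0L))
  expect_equal(beta_mntd(ab, tr, c("k", "m")), 2)

  # k = {A:3, B:1}, m = {C}: weighted mean of d=4 both directions
  wc <- cbind(k = c(A = 3L, B = 1L, C = 0L), m = c(A = 0L, B = 0L, C = 1L))
  expect_equal(beta_mntd(wc, tr, c("k", "m"), weighted = TRUE), 4)

  empty <- cbind(k = c(A = 1L, B = 0L, C = 0L), m = c(A = 0L, B = 0L, C = 0L))
  expect_error(beta_mntd(empty, tr, c("k", "m")), "empty")
})

test_that("betaMNTD agrees with an independent implementation", {
  tree <- simulate_tree(15, seed = 31)
  tab <- random_table(15, 4, lambda = 3, seed = 32)
  rownames(tab) <- tree$tip.label
  d <- patristic_distances(tree)
  ref <- as.matrix(picante::comdistnt(t(tab), d, abundance.weighted = TRUE))
  for (pr in utils::combn(colnames(tab), 2, simplify = FALSE))
    expect_equal(beta_mntd(tab, tree, pr), ref[pr[1], pr[2]])

  # unweighted: picante pools both communities in its denominator, which
  # matches the half-sum definition only at equal richness
  tabu <- matrix(0L, 15, 3,
                 dimnames = list(tree$tip.label, paste0("s", 1:3)))
  set.seed(33)
  for (j in 1:3) tabu[sample(15, 6), j] <- 1L
  refu <- as.matrix(picante::comdistnt(t(tabu), d, abundance.weighted = FALSE))
  for (pr in utils::combn(colnames(tabu), 2, simplify = FALSE))
    expect_equal(beta_mntd(tabu, tree, pr, weighted = FALSE),
                 refu[pr[1], pr[2]])
})

test_that("betaNTI results satisfy their defining identities", {
  tree <- simulate_tree(30, seed = 41)
  sc <- assembly_scenario("neutral", n_taxa = 30, n_samples = 5, depth = 300,
                          seed = 42)
  tab <- simulate_communities(tree, sc)
  res <- beta_nti(tab, tree, n_rand = 100, seed = 43)
  expect_equal(nrow(res), choose(5, 2))
  ok <- !is.na(res$beta_nti)
  expect_equal(res$beta_nti[ok],
               (res$beta_mntd_obs[ok] - res$null_mean[ok]) / res$null_sd[ok])
  expect_identical(res$assembly_class[ok],
                   ifelse(res$beta_nti[ok] < -2, "homogeneous_selection",
                          ifelse(res$beta_nti[ok] > 2, "variable_selection",
                                 "stochastic")))
  expect_error(beta_nti(tab, tree, n_rand = 10), ">= 100")
})

test_that("degenerate nulls are flagged undefined, not infinite", {
  # two taxa: every tip permutation yields the same betaMNTD
  tr <- ape::read.tree(text = "(A:1,B:1);")
  tab <- cbind(k = c(A = 1L, B = 0L), m = c(A = 0L, B = 1L))
  res <- beta_nti(tab, tr, n_rand = 100, seed = 1)
  expect_true(is.na(res$beta_nti))
  expect_true(is.na(res$assembly_class))
  expect_error(assembly_distance_matrix(res), "undefined")
})

test_that("betaNTI is invariant to consistent relabelling", {
  tree <- simulate_tree(20, seed = 51)
  sc <- assembly_scenario("neutral", n_taxa = 20, n_samples = 4, depth = 300,
                          seed = 52)
  tab <- simulate_communities(tree, sc)
  res <- beta_nti(tab, tree, n_rand = 100, seed = 53)

  relab <- stats::setNames(paste0("x", seq_len(20)), tree$tip.label)
  tree2 <- tree
  tree2$tip.label <- unname(relab[tree$tip.label])
  tab2 <- tab
  rownames(tab2) <- unname(relab[rownames(tab)])
  res2 <- beta_nti(tab2, tree2, n_rand = 100, seed = 53)
  expect_equal(res2$beta_mntd_obs, res$beta_mntd_obs)
  expect_equal(res2$beta_nti, res$beta_nti)
})

test_that("branch-length scaling shifts betaMNTD but not betaNTI", {
  tree <- simulate_tree(20, seed = 61)
  sc <- assembly_scenario("neutral", n_taxa = 20, n_samples = 4, depth = 300,
                          seed = 62)
  tab <- simulate_communities(tree, sc)
  res <- beta_nti(tab, tree, n_rand = 100, seed = 63)
  tree_c <- tree
  tree_c$edge.length <- tree$edge.length * 3.5
  res_c <- beta_nti(tab, tree_c, n_rand = 100, seed = 63)
  expect_equal(res_c$beta_mntd_obs, 3.5 * res$beta_mntd_obs)
  expect_equal(res_c$beta_nti, res$beta_nti, tolerance = 1e-10)
})

test_that("the betaNTI matrix is a valid signed symmetric export", {
  tree <- simulate_tree(40, seed = 71)
  sc <- assembly_scenario("neutral", n_taxa = 40, n_samples = 4, depth = 500,
                          seed = 72)
  tab <- simulate_communities(tree, sc)
  res <- beta_nti(tab, tree, n_rand = 100, seed = 73)
  m <- assembly_distance_matrix(res)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 4))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(m, path)
  expect_equal(read_distance_matrix(path, signed = TRUE), m,
               tolerance = 1e-12)

  expect_error(assembly_distance_matrix(res[-1, ]), "missing pair")
})
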