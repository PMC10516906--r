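# Nearest-taxon phylogenetic turnover and its null model.
#
# betaMNTD(k, m) = 1/2 [ sum_{i in k} f_ik min_{j in m} d(i, j)
#                      + sum_{j in m} f_jm min_{i in k} d(j, i) ]
# with f the within-sample relative abundances (weighted) or 1/richness
# (unweighted), d the patristic distance, and the minimum taken over taxa
# present in the other sample — a shared taxon therefore contributes 0.
# betaNTI is the z-score of the observed betaMNTD against a null built by
# shuffling taxon labels across the tips of the phylogeny of all taxa in
# the table (equivalently, permuting rows and columns of the patristic
# matrix), one shared permutation per randomization.

# row-wise minima of a matrix via max.col (fast C path, no apply)
.row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# betaMNTD for one pair given the patristic matrix and index/weight vectors
.pair_bmntd <- function(d, idx_k, idx_m, w_k, w_m) {
  sub <- d[idx_k, idx_m, drop = FALSE]
  0.5 * (sum(w_k * .row_mins(sub)) + sum(w_m * .row_mins(t(sub))))
}

# presence indices and abundance weights for every sample of a table
.sample_profiles <- function(x, weighted) {
  lapply(seq_len(ncol(x)), function(j) {
    idx <- which(x[, j] > 0)
    if (!length(idx))
      stop("sample '", colnames(x)[j], "' is empty", call. = FALSE)
    w <- if (weighted) x[idx, j] / sum(x[idx, j]) else rep(1 / length(idx), length(idx))
    list(idx = idx, w = as.numeric(w))
  })
}

.check_taxa_in_tree <- function(x, tree) {
  missing <- setdiff(rownames(x), tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Between-community beta mean nearest taxon distance
#'
#' @param x count table (taxa x samples); taxa must all be tips of
#'   \code{tree}.
#' @param tree phylogeny with branch lengths.
#' @param pair character vector of the two sample ids to compare.
#' @param weighted weight taxa by relative abundance (default) or equally
#'   (1/richness).
#' @return the betaMNTD value (phylogenetic distance units, >= 0).
#' @export
beta_mntd <- function(x, tree, pair, weighted = TRUE) {
  x <- count_table(x)
  tree <- validate_tree(tree)
  .check_taxa_in_tree(x, tree)
  if (length(pair) != 2 || !all(pair %in% colnames(x)))
    stop("pair must name two samples of the table", call. = FALSE)
  d <- patristic_distances(tree, rownames(x))
  prof <- .sample_profiles(x[, pair, drop = FALSE], weighted)
  .pair_bmntd(d, prof[[1]]$idx, prof[[2]]$idx, prof[[1]]$w, prof[[2]]$w)
}

.classify_bnti <- function(b) {
  ifelse(is.na(b), NA_character_,
         ifelse(b < -2, "homogeneous_selection",
                ifelse(b > 2, "variable_selection", "stochastic")))
}

#' beta nearest taxon index (betaNTI) for every sample pair
#'
#' For each randomization one random permutation of tip labels is applied
#' across the full phylogeny of all taxa in the table, and the null
#' betaMNTD of every sample pair is recomputed under that shared
#' permutation.  betaNTI = (observed - null mean) / null sd.  Values below
#' -2 indicate homogeneous selection (less phylogenetic turnover than the
#' stochastic expectation), above +2 variable selection, and the rest are
#' classed stochastic.  A pair whose null sd is 0 (e.g. 2-taxon tables)
#' gets an undefined (NA) betaNTI, flagged rather than clamped to +-Inf.
#'
#' @param x count table (taxa x samples, >= 2 samples).
#' @param tree phylogeny covering all table taxa.
#' @param n_rand number of tip-shuffling randomizations (>= 100; the
#'   conventional choice is 1000).
#' @param weighted abundance-weighted betaMNTD (default) or presence-only.
#' @param seed RNG seed.
#' @return data.frame, one row per unordered sample pair: \code{sample_i},
#'   \code{sample_j}, \code{beta_mntd_obs}, \code{null_mean},
#'   \code{null_sd}, \code{beta_nti}, \code{assembly_class},
#'   \code{n_randomizations}.
#' @export
beta_nti <- function(x, tree, n_rand = 1000, weighted = TRUE, seed = 1) {
  x <- count_table(x)
  tree <- validate_tree(tree)
  .check_taxa_in_tree(x, tree)
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  if (n_rand < 100) stop("n_rand must be >= 100", call. = FALSE)
  d <- patristic_distances(tree, rownames(x))
  prof <- .sample_profiles(x, weighted)
  n_s <- ncol(x)
  pairs <- utils::combn(n_s, 2)
  n_p <- ncol(pairs)

  obs <- vapply(seq_len(n_p), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    .pair_bmntd(d, prof[[a]]$idx, prof[[b]]$idx, prof[[a]]$w, prof[[b]]$w)
  }, numeric(1))

  set.seed(seed)
  n_t <- nrow(x)
  null <- matrix(NA_real_, n_rand, n_p)
  for (r in seq_len(n_rand)) {
    perm <- sample.int(n_t)
    for (p in seq_len(n_p)) {
      a <- pairs[1, p]; b <- pairs[2, p]
      null[r, p] <- .pair_bmntd(d, perm[prof[[a]]$idx], perm[prof[[b]]$idx],
                                prof[[a]]$w, prof[[b]]$w)
    }
  }
  null_mean <- colMeans(null)
  null_sd <- apply(null, 2, stats::sd)
  bnti <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, NA_real_)

  data.frame(sample_i = colnames(x)[pairs[1, ]],
             sample_j = colnames(x)[pairs[2, ]],
             beta_mntd_obs = obs,
             null_mean = null_mean,
             null_sd = null_sd,
             beta_nti = bnti,
             assembly_class = .classify_bnti(bnti),
             n_randomizations = n_rand,
             stringsAsFactors = FALSE)
}

#' Assemble per-pair betaNTI values into a labelled symmetric matrix
#'
#' The matrix of signed betaNTI scores is the "assembly process" input to
#' Mantel distance-matrix regressions.
#'
#' @param results data.frame from \code{\link{beta_nti}}; must cover every
#'   pair of its samples and contain no undefined betaNTI.
#' @return symmetric labelled matrix of signed betaNTI, zero diagonal.
#' @export
assembly_distance_matrix <- function(results) {
  samples <- sort(unique(c(results$sample_i, results$sample_j)))
  if (anyNA(results$beta_nti))
    stop("undefined betaNTI for pair(s): ",
         paste(paste(results$sample_i, results$sample_j, sep = "~")[
           is.na(results$beta_nti)], collapse = ", "), call. = FALSE)
  n <- length(samples)
  m <- matrix(NA_real_, n, n, dimnames = list(samples, samples))
  diag(m) <- 0
  i <- match(results$sample_i, samples)
  j <- match(results$sample_j, samples)
  m[cbind(i, j)] <- results$beta_nti
  m[cbind(j, i)] <- results$beta_nti
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing pair(s): ",
         paste(samples[miss[, 1]], samples[miss[, 2]], sep = "~", collapse = ", "),
         call. = FALSE)
  }
  validate_distance_matrix(m, signed = TRUE)
}
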