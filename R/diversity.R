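#' Rarefy a count table to even depth
#'
#' Each sample is subsampled once, without replacement (multivariate
#' hypergeometric), to exactly \code{depth} reads.  Samples whose total is
#' below \code{depth} are dropped with a warning rather than erroring — a
#' study typically rarefies to its own minimum depth so the case does not
#' arise there, but the behaviour must be predictable.
#'
#' @param x count table (taxa x samples).
#' @param depth target depth (>= 1).
#' @param seed RNG seed; the draw is deterministic given it.
#' @return rarefied count table; every column sums to exactly \code{depth}.
#' @export
rarefy <- function(x, depth, seed = 1) {
  x <- count_table(x)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  totals <- colSums(x)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples have fewer than ", depth, " reads", call. = FALSE)
  if (any(!keep))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(x)[!keep], collapse = ", "), call. = FALSE)
  x <- x[, keep, drop = FALSE]
  set.seed(seed)
  # vegan rarefies rows, and a sample already at depth is left untouched;
  # its "observed counts" advisory is spurious here (inputs are validated
  # integer counts)
  out <- t(suppressWarnings(vegan::rrarefy(t(x), sample = depth)))
  count_table(out)
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum |x_t - y_t| / sum (x_t + y_t), in [0, 1].
#'
#' @param x count (or abundance) table, taxa x samples, >= 2 samples.
#' @return labelled symmetric distance matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  if (ncol(x) < 2) stop("need >= 2 samples", call. = FALSE)
  zero <- colSums(x) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(x)[zero], collapse = ", "),
         call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  diag(d) <- 0
  validate_distance_matrix(d)
}

#' Nonmetric multidimensional scaling (NMDS)
#'
#' Kruskal's nonmetric MDS with monotone regression, minimizing stress-1.
#' The first start is the metric (principal-coordinates) configuration;
#' the remaining restarts are random.  The lowest-stress solution is
#' returned with coordinates centred per axis.
#'
#' @param dm labelled distance matrix.
#' @param k target dimensionality (k < number of samples).
#' @param n_restarts random restarts after the metric start.
#' @param max_iter iteration cap per start.
#' @param seed RNG seed for the random starts.
#' @return list: \code{points} (samples x k), \code{stress} (stress-1, in
#'   [0, 1]), \code{n_restarts}.
#' @export
nmds <- function(dm, k = 2, n_restarts = 20, max_iter = 300, seed = 1) {
  dm <- validate_distance_matrix(dm)
  n <- nrow(dm)
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  d <- stats::as.dist(dm)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts + 1)) {
    y0 <- if (r == 1) {
      stats::cmdscale(d, k = k)
    } else {
      matrix(stats::rnorm(n * k), n, k)
    }
    fit <- vegan::monoMDS(d, y = y0, k = k, maxit = max_iter,
                          smin = 1e-7, sratmax = 1 - 1e-7)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  list(points = pts, stress = best$stress, n_restarts = n_restarts)
}

#' PERMANOVA on a distance matrix
#'
#' Anderson's distance-based pseudo-F with free permutation of group
#' labels; p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param dm labelled distance matrix.
#' @param groups group label per sample (named by sample, or in matrix
#'   order); >= 2 groups with >= 2 samples each.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: \code{f} pseudo-F, \code{r2}, \code{p}, \code{n_perm}.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = 1) {
  dm <- validate_distance_matrix(dm)
  if (!is.null(names(groups))) {
    missing <- setdiff(rownames(dm), names(groups))
    if (length(missing))
      stop("no group label for sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    groups <- groups[rownames(dm)]
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(groups)) < 2)
    stop("every group needs >= 2 samples", call. = FALSE)
  set.seed(seed)
  df <- data.frame(group = groups)
  fit <- vegan::adonis2(stats::as.dist(dm) ~ group, data = df,
                        permutations = n_perm)
  list(f = fit$F[1], r2 = fit$R2[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}
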