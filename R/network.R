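# Random-matrix-theory thresholding of taxon co-occurrence correlations.
#
# The eigenvalue nearest-neighbour spacing distribution (NNSD) of a
# correlation matrix thresholded at s follows GOE (Wigner-Dyson) statistics
# while random noise correlations remain, and transitions to Poisson
# statistics once only non-random structure is left.  The chosen network
# cutoff s* is the smallest threshold at which the NNSD is consistent with
# Poisson and stays consistent at every larger tested threshold.

#' Pearson correlation matrix of taxon abundance profiles
#'
#' Taxa below the prevalence cutoff are removed first (sparse taxa produce
#' spurious perfect correlations); the default transform is log10 relative
#' abundance with zeros replaced by a pseudo-fraction (a configurable
#' multiple of the smallest nonzero relative abundance in the table).
#' Zero-variance taxa after the transform are excluded with a warning.
#'
#' @param x count table (taxa x samples, >= 10 samples).
#' @param transform \code{"log_relative"} (default; log10 relative
#'   abundance, appropriate for compositional amplicon data),
#'   \code{"log_counts"} (log10 of counts + 1, for abundance data that is
#'   not sum-constrained) or \code{"none"}.
#' @param prevalence minimum fraction of samples a taxon must occur in
#'   (default 0.5).
#' @param pseudo_zero_factor zeros are replaced by this multiple of the
#'   smallest nonzero relative abundance before the log.
#' @return symmetric Pearson r matrix with unit diagonal, labelled by the
#'   retained taxa.
#' @export
correlation_matrix <- function(x, transform = c("log_relative", "log_counts",
                                                "none"),
                               prevalence = 0.5, pseudo_zero_factor = 0.01) {
  transform <- match.arg(transform)
  x <- count_table(x)
  if (ncol(x) < 10) stop("need >= 10 samples for co-occurrence analysis", call. = FALSE)
  keep <- rowMeans(x > 0) >= prevalence
  if (sum(keep) < 2)
    stop("fewer than 2 taxa pass the prevalence filter", call. = FALSE)
  x <- x[keep, , drop = FALSE]
  if (transform == "log_relative") {
    rel <- sweep(x, 2, colSums(x), "/")
    pseudo <- pseudo_zero_factor * min(rel[rel > 0])
    rel[rel == 0] <- pseudo
    y <- log10(rel)
  } else if (transform == "log_counts") {
    y <- log10(x + 1)
  } else {
    y <- x
  }
  v <- apply(y, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance taxa: ",
            paste(rownames(y)[v == 0], collapse = ", "), call. = FALSE)
    y <- y[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(y))
  diag(r) <- 1
  r
}

# threshold a correlation matrix: zero |r| < s off-diagonal, keep diagonal
.threshold_matrix <- function(r, s) {
  out <- r
  out[abs(out) < s] <- 0
  diag(out) <- diag(r)
  out
}

#' Nearest-neighbour spacing distribution of a thresholded matrix
#'
#' Entries with |r| < s are zeroed, rows/columns left with no off-diagonal
#' entry are dropped, and the eigenvalues of the remaining symmetric matrix
#' are unfolded: numerically coincident eigenvalues are collapsed, then the
#' empirical cumulative eigenvalue count is smoothed with a cubic smoothing
#' spline (8 knots) and each eigenvalue is mapped through it, so the
#' nearest-neighbour spacings have mean 1.  The spacing histogram (width
#' 0.1 on [0, 3], plus a tail bin) is tested by chi-square against the
#' Poisson form exp(-d) and the GOE Wigner surmise (pi d / 2) exp(-pi d^2 / 4).
#'
#' @param r symmetric correlation matrix.
#' @param s threshold in [0, 1).
#' @param min_eigen minimum number of distinct eigenvalues required.
#' @return list: \code{s}, \code{n_eigen}, \code{spacings},
#'   \code{chisq_poisson}, \code{chisq_goe}, \code{p_poisson} (chi-square
#'   p-value of the Poisson fit), \code{poisson_like} (logical).
#' @export
nnsd <- function(r, s, min_eigen = 20) {
  m <- .threshold_matrix(r, s)
  connected <- rowSums(abs(m) > 0) > 1  # an off-diagonal survivor besides diag
  m <- m[connected, connected, drop = FALSE]
  if (nrow(m) < min_eigen)
    stop("only ", nrow(m), " rows retained at s = ", s,
         "; NNSD unstable below ", min_eigen, call. = FALSE)
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  # collapse numerically repeated eigenvalues: spacings of exact degeneracies
  # are an artefact of sparsity, not of the spacing law
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  if (length(ev) < min_eigen)
    stop("only ", length(ev), " distinct eigenvalues at s = ", s,
         "; NNSD unstable below ", min_eigen, call. = FALSE)
  n <- length(ev)
  # unfold: smoothed cumulative count, spacings on the unfolded scale
  fit <- stats::smooth.spline(ev, seq_len(n), nknots = min(8, n - 4))
  unfolded <- stats::predict(fit, ev)$y
  spacings <- diff(unfolded)
  spacings[spacings < 0] <- 0
  spacings <- spacings / mean(spacings)

  breaks <- c(seq(0, 3, by = 0.1), Inf)
  obs <- as.vector(table(cut(spacings, breaks, right = FALSE)))
  n_sp <- length(spacings)
  p_pois <- diff(stats::pexp(breaks, rate = 1))
  p_goe <- diff(1 - exp(-pi * pmin(breaks, 1e6)^2 / 4))
  chisq <- function(p_exp) {
    e <- n_sp * p_exp
    ok <- e > 0
    sum((obs[ok] - e[ok])^2 / e[ok])
  }
  cs_p <- chisq(p_pois)
  cs_g <- chisq(p_goe)
  df <- sum(n_sp * p_pois > 0) - 1
  p_poisson <- stats::pchisq(cs_p, df = df, lower.tail = FALSE)
  list(s = s, n_eigen = n, spacings = spacings,
       chisq_poisson = cs_p, chisq_goe = cs_g,
       p_poisson = p_poisson, poisson_like = cs_p < cs_g)
}

#' RMT threshold scan
#'
#' Scans the threshold grid and returns the smallest s whose NNSD is
#' consistent with Poisson statistics (chi-square p > 0.05) and remains so
#' persistently — at a fraction of at least \code{persistence} of the
#' larger tested thresholds that still yield enough eigenvalues (the
#' chi-square p fluctuates from threshold to threshold on matrices of a
#' few dozen taxa, so demanding consistency at literally every larger s
#' rejects clearly modular matrices).  The full scan log is attached.
#'
#' @param r correlation matrix.
#' @param s_grid thresholds to scan (default 0.30 to 0.95 by 0.01).
#' @param p_cut Poisson-consistency level.
#' @param persistence required fraction of Poisson-consistent thresholds
#'   above s*.
#' @param min_eigen minimum distinct eigenvalues per evaluable threshold.
#' @return list: \code{s_star}, \code{scan} (data.frame s, n_eigen,
#'   chisq_poisson, chisq_goe, p_poisson).
#' @export
rmt_threshold <- function(r, s_grid = seq(0.30, 0.95, by = 0.01),
                          p_cut = 0.05, persistence = 0.9, min_eigen = 20) {
  if (any(s_grid <= 0 | s_grid >= 1)) stop("s_grid must lie in (0, 1)", call. = FALSE)
  s_grid <- sort(s_grid)
  scan <- data.frame(s = s_grid, n_eigen = NA_integer_,
                     chisq_poisson = NA_real_, chisq_goe = NA_real_,
                     p_poisson = NA_real_)
  for (i in seq_along(s_grid)) {
    rep_i <- tryCatch(nnsd(r, s_grid[i], min_eigen = min_eigen),
                      error = function(e) NULL)
    if (is.null(rep_i)) next
    scan$n_eigen[i] <- rep_i$n_eigen
    scan$chisq_poisson[i] <- rep_i$chisq_poisson
    scan$chisq_goe[i] <- rep_i$chisq_goe
    scan$p_poisson[i] <- rep_i$p_poisson
  }
  evaluable <- which(!is.na(scan$p_poisson))
  if (!length(evaluable)) {
    stop("no threshold in the grid could be evaluated; scan log:\n",
         paste(utils::capture.output(print(scan)), collapse = "\n"), call. = FALSE)
  }
  consistent <- scan$p_poisson[evaluable] > p_cut
  # smallest s consistent at itself and at >= `persistence` of the larger
  # evaluable thresholds (inclusive tail fraction)
  n_c <- length(consistent)
  tail_frac <- rev(cumsum(rev(consistent))) / (n_c - seq_len(n_c) + 1)
  ok <- consistent & tail_frac >= persistence
  if (!any(ok))
    stop("no threshold with persistent Poisson-consistent NNSD; scan log:\n",
         paste(utils::capture.output(print(scan[evaluable, ])), collapse = "\n"),
         call. = FALSE)
  s_star <- s_grid[evaluable[which(ok)[1]]]
  list(s_star = s_star, scan = scan)
}

#' Build a co-occurrence network at a chosen threshold
#'
#' Edges are the taxon pairs with |r| >= s* (or r >= s* when
#' \code{positive_only}); node degree counts retained incident edges;
#' isolated taxa are dropped by default.
#'
#' @param r correlation matrix.
#' @param s_star correlation threshold, from \code{\link{rmt_threshold}} or
#'   user-supplied.
#' @param positive_only keep only positive correlations (the
#'   positive-interaction subnetwork).
#' @param taxonomy optional free-text label per taxon (named by taxon id).
#' @param keep_isolated keep degree-0 nodes.
#' @return object of class \code{network_model}: \code{nodes},
#'   \code{edges} (taxon_i, taxon_j, r, sign), \code{degree}, \code{s_star},
#'   \code{positive_only}, \code{taxonomy}.
#' @export
build_network <- function(r, s_star, positive_only = FALSE, taxonomy = NULL,
                          keep_isolated = FALSE) {
  stopifnot(nrow(r) == ncol(r))
  taxa <- rownames(r)
  sel <- if (positive_only) r >= s_star else abs(r) >= s_star
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
                      r = r[idx],
                      sign = ifelse(r[idx] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  degree <- stats::setNames(integer(length(taxa)), taxa)
  if (nrow(edges)) {
    tab <- table(c(edges$taxon_i, edges$taxon_j))
    degree[names(tab)] <- as.integer(tab)
  } else {
    warning("no edges retained at s* = ", s_star, call. = FALSE)
  }
  nodes <- if (keep_isolated) taxa else taxa[degree > 0]
  structure(list(nodes = nodes, edges = edges, degree = degree[nodes],
                 s_star = s_star, positive_only = positive_only,
                 taxonomy = if (!is.null(taxonomy)) taxonomy[nodes] else NULL),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("co-occurrence network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (s* = ", x$s_star,
      if (x$positive_only) ", positive only" else "", ")\n", sep = "")
  invisible(x)
}
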