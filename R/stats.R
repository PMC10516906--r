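# Permutation and screening statistics used downstream of the community
# analyses.  All permutation p-values use the (1 + count) / (1 + n_perm)
# estimator, so p = 0 never occurs.

.upper_tri_values <- function(m) m[upper.tri(m)]

#' Mantel distance-matrix regression
#'
#' Correlation between the upper-triangle entries of two labelled distance
#' (or signed score) matrices, with a null built by permuting rows and
#' columns of the second matrix with one shared permutation; two-sided
#' p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_perm).
#'
#' @param dm_x,dm_y labelled square symmetric matrices over the same
#'   samples (aligned by label; order may differ).
#' @param kind \code{"pearson"} or \code{"spearman"}.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: \code{r}, \code{p}, \code{n_perm}, \code{kind}.
#' @export
mantel <- function(dm_x, dm_y, kind = c("pearson", "spearman"),
                   n_perm = 999, seed = 1) {
  kind <- match.arg(kind)
  dm_x <- validate_distance_matrix(dm_x, signed = TRUE)
  dm_y <- validate_distance_matrix(dm_y, signed = TRUE)
  if (!setequal(rownames(dm_x), rownames(dm_y)))
    stop("distance matrices cover different samples", call. = FALSE)
  dm_y <- dm_y[rownames(dm_x), rownames(dm_x)]
  n <- nrow(dm_x)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  x <- .upper_tri_values(dm_x)
  if (stats::sd(x) == 0 || stats::sd(.upper_tri_values(dm_y)) == 0)
    stop("constant distance matrix; correlation undefined", call. = FALSE)
  r_obs <- stats::cor(x, .upper_tri_values(dm_y), method = kind)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_p <- stats::cor(x, .upper_tri_values(dm_y[perm, perm]), method = kind)
    if (abs(r_p) >= abs(r_obs)) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (1 + n_perm), n_perm = n_perm, kind = kind)
}

#' Rank-sum screen for shifted features versus a reference group
#'
#' Wilcoxon rank-sum test per feature (exact null distribution when the
#' combined n is small and tie-free, normal approximation with tie
#' correction otherwise — \code{stats::wilcox.test} semantics), followed by
#' Benjamini-Hochberg correction across all features in the screen.  The
#' default alternative asks for decreased abundance in the treatment group
#' relative to the reference.
#'
#' @param features feature x sample matrix.
#' @param groups group label per sample (in column order or named).
#' @param reference_group label of the reference group.
#' @param treatment_group optional label to test against the reference;
#'   default: all non-reference samples pooled (use one label per call when
#'   screening several treatments).
#' @param alternative \code{"decrease"}, \code{"increase"} or
#'   \code{"two_sided"} — direction of change in the treatment group.
#' @param alpha significance level on the adjusted p.
#' @return data.frame per feature: medians, statistic \code{w}, \code{p},
#'   \code{p_adj} (BH), \code{direction} of the median difference,
#'   \code{constant} flag, \code{significant} flag.
#' @export
wilcoxon_screen <- function(features, groups, reference_group,
                            treatment_group = NULL,
                            alternative = c("decrease", "increase", "two_sided"),
                            alpha = 0.05) {
  alternative <- match.arg(alternative)
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(features)]
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' not present", call. = FALSE)
  ref_idx <- which(groups == reference_group)
  trt_idx <- if (is.null(treatment_group)) which(groups != reference_group)
             else which(groups == treatment_group)
  if (length(ref_idx) < 3 || length(trt_idx) < 3)
    stop("need >= 3 samples per group", call. = FALSE)
  alt <- switch(alternative, decrease = "less", increase = "greater",
                two_sided = "two.sided")
  res <- t(vapply(seq_len(nrow(features)), function(i) {
    trt <- features[i, trt_idx]
    ref <- features[i, ref_idx]
    if (stats::sd(c(trt, ref)) == 0)
      return(c(w = NA_real_, p = 1, med_trt = stats::median(trt),
               med_ref = stats::median(ref), constant = 1))
    wt <- suppressWarnings(stats::wilcox.test(trt, ref, alternative = alt))
    c(w = unname(wt$statistic), p = wt$p.value, med_trt = stats::median(trt),
      med_ref = stats::median(ref), constant = 0)
  }, numeric(5)))
  out <- data.frame(feature = rownames(features),
                    median_treatment = res[, "med_trt"],
                    median_reference = res[, "med_ref"],
                    w = res[, "w"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
                    direction = ifelse(res[, "med_trt"] < res[, "med_ref"],
                                       "decreased",
                                       ifelse(res[, "med_trt"] > res[, "med_ref"],
                                              "increased", "unchanged")),
                    constant = res[, "constant"] == 1,
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha & !out$constant
  out
}

# compact letter display: groups sharing a letter form a maximal clique of
# the "not significantly different" graph, so each maximal clique gets one
# letter and every group collects the letters of its cliques
.letter_display <- function(differs) {
  g <- rownames(differs)
  same <- !differs
  diag(same) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(same, mode = "undirected")
  cliques <- igraph::max_cliques(gr)
  # stable order: by smallest member index, so letter 'a' starts at group 1
  ord <- order(vapply(cliques, function(cl) min(as.integer(cl)), numeric(1)))
  cliques <- cliques[ord]
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(cliques))
    for (gg in g[as.integer(cliques[[k]])])
      letters_out[gg] <- paste0(letters_out[gg], letters[k])
  letters_out
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' F test across groups, Tukey honest significant differences on the
#' studentized-range distribution, and the usual figure convention: groups
#' sharing a letter do not differ at \code{alpha}.
#'
#' @param values numeric response.
#' @param groups group label per value (>= 2 groups, >= 2 each).
#' @param alpha significance level for the pairwise comparisons.
#' @return list: \code{f}, \code{p} (ANOVA), \code{tukey} (pairwise
#'   data.frame), \code{letters} (named per-group letter display).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(groups)) < 2) stop("need >= 2 samples per group", call. = FALSE)
  if (all(tapply(values, groups, stats::sd) == 0))
    stop("zero within-group variance everywhere; ANOVA undefined", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  lv <- levels(groups)
  differs <- matrix(FALSE, nlevels(groups), nlevels(groups),
                    dimnames = list(lv, lv))
  for (i in seq_along(cmp)) {
    a <- cmp[[i]][1]; b <- cmp[[i]][2]
    differs[a, b] <- differs[b, a] <- tk[i, "p adj"] < alpha
  }
  list(f = an$`F value`[1], p = an$`Pr(>F)`[1],
       tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL,
                          check.names = FALSE),
       letters = .letter_display(differs))
}

#' Z-score transform per feature
#'
#' @param x numeric vector, or feature x sample matrix transformed row-wise.
#' @return same shape, each feature centred to mean 0 and scaled to sample
#'   sd 1 (n - 1 denominator).
#' @export
zscore <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, zscore))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  if (length(x) < 2) stop("need >= 2 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0)
    stop("zero variance", if (!is.null(attr(x, "feature"))) paste0(" in ", attr(x, "feature")),
         call. = FALSE)
  (x - mean(x)) / s
}

#' RPKM normalization of a gene table
#'
#' RPKM = count / ((gene length / 1000) * (total mapped reads / 1e6)).
#'
#' @param genes a \code{\link{gene_table}}.
#' @return gene x sample matrix of RPKM values.
#' @export
rpkm <- function(genes) {
  if (any(genes$total_mapped == 0))
    stop("zero total mapped reads for sample(s): ",
         paste(colnames(genes$counts)[genes$total_mapped == 0], collapse = ", "),
         call. = FALSE)
  kb <- genes$gene_lengths / 1000
  per_m <- genes$total_mapped / 1e6
  sweep(genes$counts / kb, 2, per_m, "/")
}

#' Permutation test of an ordinary least-squares slope
#'
#' @param x,y paired observations (n >= 4).
#' @param n_perm permutations of y against x.
#' @param seed RNG seed.
#' @return list: \code{slope}, \code{intercept}, \code{p} (two-sided
#'   permutation p), \code{n_perm}.
#' @export
permutation_slope_test <- function(x, y, n_perm = 999, seed = 1) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 4) stop("need >= 4 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x; slope undefined", call. = FALSE)
  slope_of <- function(yy) stats::cov(x, yy) / stats::var(x)
  b_obs <- slope_of(y)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm))
    if (abs(slope_of(sample(y))) >= abs(b_obs)) count <- count + 1L
  list(slope = b_obs, intercept = mean(y) - b_obs * mean(x),
       p = (1 + count) / (1 + n_perm), n_perm = n_perm)
}
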