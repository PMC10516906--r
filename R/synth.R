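#' Simulate a rooted phylogeny
#'
#' Random rooted binary topology with independent exponential branch
#' lengths (mean 1) — a pure-birth-style tree giving every tip a positive
#' patristic distance to every other tip.  Deterministic given \code{seed}.
#'
#' @param n_taxa number of tips (>= 2); tips are labelled t1..tN.
#' @param seed integer RNG seed.
#' @return an \code{ape} \code{phylo}.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = TRUE, br = stats::rexp)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  validate_tree(tr)
}

#' Describe a community-assembly simulation scenario
#'
#' @param regime one of \code{"neutral"}, \code{"homogeneous_selection"},
#'   \code{"variable_selection"}.
#' @param n_taxa,n_samples community dimensions (n_taxa >= 4).
#' @param depth sequencing depth per sample (>= 100).  Scalar or one per
#'   sample.
#' @param selection_strength sigma of the Gaussian environmental filter on
#'   the Brownian trait, in trait standard-deviation units.
#' @param trait_sigma Brownian-motion rate (variance per unit branch length)
#'   of the niche trait evolved along the tree.
#' @param meta_sdlog log-normal sd of metacommunity abundances (dominance
#'   structure; 1.5 gives the strong dominance typical of phototrophic
#'   biofilms).
#' @param n_blocks number of sample blocks with distinct optima under
#'   variable selection.
#' @param sample_noise_sdlog log-normal sd of per-sample, per-taxon
#'   abundance noise (ecological drift between replicate samples); 0
#'   disables it.
#' @param seed integer RNG seed.
#' @return classed list of scenario parameters.
#' @export
assembly_scenario <- function(regime = c("neutral", "homogeneous_selection",
                                         "variable_selection"),
                              n_taxa = 60, n_samples = 10, depth = 2000,
                              selection_strength = 0.5, trait_sigma = 1,
                              meta_sdlog = 1.5, n_blocks = 2,
                              sample_noise_sdlog = 1, seed = 1) {
  regime <- match.arg(regime)
  if (n_taxa < 4) stop("n_taxa must be >= 4", call. = FALSE)
  if (any(depth < 100)) stop("depth must be >= 100", call. = FALSE)
  if (selection_strength < 0) stop("selection_strength must be >= 0", call. = FALSE)
  structure(list(regime = regime, n_taxa = n_taxa, n_samples = n_samples,
                 depth = depth, selection_strength = selection_strength,
                 trait_sigma = trait_sigma, meta_sdlog = meta_sdlog,
                 n_blocks = n_blocks, sample_noise_sdlog = sample_noise_sdlog,
                 seed = seed),
            class = "assembly_scenario")
}

#' Simulate communities under a known assembly regime
#'
#' All regimes draw each sample as a multinomial of size \code{depth} from
#' a shared log-normal metacommunity frequency vector.  Under selection a
#' niche trait is first evolved by Brownian motion along the tree and the
#' metacommunity frequencies are reweighted by a Gaussian environmental
#' filter exp(-(trait - opt)^2 / (2 sigma^2)): a single shared optimum
#' (homogeneous selection, low phylogenetic turnover) or block-specific
#' optima at least 4 sigma apart (variable selection, high turnover).
#' Per-sample log-normal abundance noise emulates ecological drift between
#' replicate samples, so samples are overlapping but distinct draws from
#' the (filtered) metacommunity.
#'
#' @param tree phylogeny whose tips cover the scenario's taxa (the first
#'   \code{n_taxa} tips are used).
#' @param scenario an \code{\link{assembly_scenario}}.
#' @return count table (taxa x samples) with attributes \code{regime},
#'   \code{trait} and \code{optima} recording the ground truth.
#' @export
simulate_communities <- function(tree, scenario) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  tree <- validate_tree(tree)
  if (length(tree$tip.label) < scenario$n_taxa)
    stop("tree has fewer tips than scenario taxa", call. = FALSE)
  taxa <- tree$tip.label[seq_len(scenario$n_taxa)]
  set.seed(scenario$seed)
  meta <- stats::rlnorm(scenario$n_taxa, meanlog = 0, sdlog = scenario$meta_sdlog)
  meta <- meta / sum(meta)
  names(meta) <- taxa

  trait <- NULL
  optima <- NULL
  weights <- matrix(1, scenario$n_taxa, scenario$n_samples)
  if (scenario$regime != "neutral") {
    trait <- ape::rTraitCont(tree, model = "BM",
                             sigma = sqrt(scenario$trait_sigma))[taxa]
    # work in standardized trait units so selection_strength is comparable
    # across trees
    trait <- (trait - mean(trait)) / stats::sd(trait)
    sg <- scenario$selection_strength
    if (scenario$regime == "homogeneous_selection") {
      optima <- rep(stats::quantile(trait, 0.8, names = FALSE), scenario$n_samples)
    } else {
      # block optima pushed to the trait extremes; guarantee >= 4 sigma
      # separation between consecutive block optima
      blocks <- rep(seq_len(scenario$n_blocks), length.out = scenario$n_samples)
      blocks <- sort(blocks)
      span <- max(diff(range(trait)), 4 * sg * (scenario$n_blocks - 1))
      opts <- min(trait) + (seq_len(scenario$n_blocks) - 1) /
        max(1, scenario$n_blocks - 1) * span
      optima <- opts[blocks]
    }
    for (j in seq_len(scenario$n_samples)) {
      w <- exp(-(trait - optima[j])^2 / (2 * sg^2))
      if (!any(meta * w > 0) || all(!is.finite(w)) || sum(meta * w) == 0)
        stop("environmental filter underflowed for every taxon; ",
             "increase selection_strength (sigma)", call. = FALSE)
      weights[, j] <- w
    }
  }

  depth <- rep(scenario$depth, length.out = scenario$n_samples)
  if (any(depth == 0)) stop("depth 0 is not allowed", call. = FALSE)
  counts <- matrix(0L, scenario$n_taxa, scenario$n_samples,
                   dimnames = list(taxa, paste0("s", seq_len(scenario$n_samples))))
  for (j in seq_len(scenario$n_samples)) {
    p <- meta * weights[, j]
    if (scenario$sample_noise_sdlog > 0)
      p <- p * stats::rlnorm(scenario$n_taxa, 0, scenario$sample_noise_sdlog)
    counts[, j] <- stats::rmultinom(1, size = depth[j], prob = p / sum(p))
  }
  out <- count_table(counts)
  attr(out, "regime") <- scenario$regime
  attr(out, "trait") <- trait
  attr(out, "optima") <- optima
  out
}

#' Describe a planted-module co-occurrence scenario
#'
#' @param n_taxa total taxa, partitioned evenly into \code{n_modules}
#'   (or pass \code{modules} explicitly as an integer vector of length
#'   n_taxa).
#' @param n_modules number of planted modules.
#' @param modules optional explicit module assignment.
#' @param rho within-module correlation of log abundance, in [0, 1].
#' @param noise_sd sd of the idiosyncratic log-abundance noise.
#' @param n_samples number of samples (>= 10; correlations are unstable
#'   below that).
#' @param mean_log mean log10-scale abundance level.
#' @param seed RNG seed.
#' @export
network_scenario <- function(n_taxa = 40, n_modules = 2, modules = NULL,
                             rho = 0.9, noise_sd = 1, n_samples = 60,
                             mean_log = 3, seed = 1) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (is.null(modules))
    modules <- sort(rep(seq_len(n_modules), length.out = n_taxa))
  if (length(modules) != n_taxa)
    stop("modules must assign every taxon", call. = FALSE)
  structure(list(n_taxa = n_taxa, modules = as.integer(modules), rho = rho,
                 noise_sd = noise_sd, n_samples = n_samples,
                 mean_log = mean_log, seed = seed),
            class = "network_scenario")
}

#' Simulate a count table with planted co-occurrence modules
#'
#' One latent Gaussian factor per module and per sample; each taxon's log
#' abundance is sqrt(rho) * (module factor) + sqrt(1 - rho) * noise, so the
#' expected within-module pairwise correlation of log abundance is rho and
#' the between-module correlation is 0.  Log abundances are exponentiated
#' (base 10) and rounded to counts.
#'
#' @param scenario a \code{\link{network_scenario}}.
#' @return count table (taxa x samples) with attribute \code{modules}.
#' @export
simulate_cooccurrence <- function(scenario) {
  stopifnot(inherits(scenario, "network_scenario"))
  if (scenario$n_samples < 10)
    stop("need >= 10 samples; pairwise correlations are unstable below that",
         call. = FALSE)
  set.seed(scenario$seed)
  n <- scenario$n_taxa
  m <- scenario$n_samples
  k <- max(scenario$modules)
  factors <- matrix(stats::rnorm(k * m), k, m)
  noise <- matrix(stats::rnorm(n * m, sd = scenario$noise_sd), n, m)
  z <- sqrt(scenario$rho) * factors[scenario$modules, , drop = FALSE] +
    sqrt(1 - scenario$rho) * noise
  loglevel <- scenario$mean_log + 0.5 * z
  counts <- round(10^loglevel)
  dimnames(counts) <- list(paste0("t", seq_len(n)), paste0("s", seq_len(m)))
  out <- count_table(counts)
  attr(out, "modules") <- stats::setNames(scenario$modules, rownames(out))
  out
}

#' Simulate a feature table with known group shifts
#'
#' Log-normal feature intensities; a flagged subset of features has its
#' log-scale mean shifted by \code{effect_size} standard deviations in
#' every non-reference group (downward by default, emulating a screen for
#' decreased abundance versus a reference light treatment).
#'
#' @param n_features number of features (rows).
#' @param groups character vector of group labels, one per sample
#'   (>= 2 groups, >= 3 samples each); the first unique label is the
#'   reference.
#' @param effect_size shift in within-group sd units (>= 0).
#' @param prop_shifted fraction of features truly shifted.
#' @param direction \code{"decrease"} or \code{"increase"} in non-reference
#'   groups.
#' @param sdlog within-group log-scale sd.
#' @param seed RNG seed.
#' @return list: \code{features} (feature x sample matrix), \code{groups},
#'   \code{truth} (character vector of truly shifted feature ids).
#' @export
simulate_feature_table <- function(n_features = 100, groups, effect_size = 2,
                                   prop_shifted = 0.2,
                                   direction = c("decrease", "increase"),
                                   sdlog = 1, seed = 1) {
  direction <- match.arg(direction)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(groups)) < 3) stop("need >= 3 samples per group", call. = FALSE)
  set.seed(seed)
  n_s <- length(groups)
  base_mu <- stats::rnorm(n_features, mean = 5, sd = 1)
  x <- matrix(stats::rnorm(n_features * n_s, mean = base_mu, sd = sdlog),
              n_features, n_s)
  n_shift <- if (effect_size == 0) 0L else round(prop_shifted * n_features)
  shifted <- if (n_shift > 0) sort(sample.int(n_features, n_shift)) else integer(0)
  ref <- groups == groups[1]
  sgn <- if (direction == "decrease") -1 else 1
  if (length(shifted))
    x[shifted, !ref] <- x[shifted, !ref] + sgn * effect_size * sdlog
  x <- exp(x)
  dimnames(x) <- list(paste0("f", seq_len(n_features)), paste0("s", seq_len(n_s)))
  list(features = x, groups = stats::setNames(groups, colnames(x)),
       truth = rownames(x)[shifted])
}
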