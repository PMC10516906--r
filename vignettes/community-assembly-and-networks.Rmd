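---
title: "Phylogenetic null models, RMT networks, and permutation statistics for microbiome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic null models, RMT networks, and permutation statistics for microbiome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmena)
```

## What this package computes

`pmena` implements the downstream inference stages used to study how an
environmental driver (in the motivating system, the colour of artificial
light on phototrophic biofilm communities) restructures a microbiome:

1. **Community assembly processes** via the between-community
   β-mean-nearest-taxon distance (βMNTD) and its null-model z-score, the
   β-nearest-taxon index (βNTI);
2. **Co-occurrence networks** with a correlation threshold chosen by the
   random-matrix-theory (RMT) transition of the eigenvalue
   nearest-neighbour spacing distribution (NNSD);
3. **Distance-matrix and screening statistics**: Mantel permutation
   regressions, PERMANOVA, NMDS, a Wilcoxon rank-sum decrease screen with
   Benjamini–Hochberg control, one-way ANOVA with Tukey letters, and the
   RPKM / rarefaction / Z-score normalizations these analyses sit on.

Every stage can be exercised on synthetic communities with known ground
truth, generated by the package itself, which is how the test suite and
the acceptance script validate the methods without any external data.

## The βMNTD/βNTI model

For two communities $k$ and $m$ with within-sample relative abundances
$f$, patristic distance $d$ between tree tips, and minima taken over taxa
present in the *other* community,

$$\beta\mathrm{MNTD}(k,m) = \tfrac{1}{2}\Big[
  \sum_{i \in k} f_{ik} \min_{j \in m} d(i,j) +
  \sum_{j \in m} f_{jm} \min_{i \in k} d(j,i) \Big].$$

A taxon shared by both communities contributes a nearest-taxon distance of
zero. The null model applies one random permutation of tip labels across
the full phylogeny of all taxa in the table per randomization
(equivalently a simultaneous row/column permutation of the patristic
matrix) and recomputes βMNTD for every pair under the shared permutation;
1000 randomizations by default. Then

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{\mathrm{obs}} -
  \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}},$$

with βNTI < −2 read as homogeneous selection (less phylogenetic turnover
than expected under stochastic assembly), βNTI > +2 as variable selection,
and the remainder as stochastic. Pairs whose null standard deviation is
zero (possible for tiny taxon sets, where every permutation yields the same
βMNTD) are flagged undefined rather than clamped to ±∞, and the βNTI
matrix export refuses to emit them silently.

Design points worth knowing:

* **Abundance weighting** is the default (`weighted = TRUE`); the
  unweighted variant divides by richness per community. Note that some
  implementations (e.g. picante's `comdistnt`) pool both communities in
  the unweighted denominator; the two definitions agree at equal richness.
* βMNTD scales linearly with branch lengths while βNTI is invariant to
  them (both properties are tested).
* The Monte-Carlo null is validated against exhaustive enumeration of all
  $5! = 120$ tip permutations on a 5-taxon instance, with βMNTD computed
  by an independent implementation.

## The synthetic community generator

`simulate_communities()` draws each sample as a multinomial of fixed depth
from a shared log-normal metacommunity (σ_log = 1.5 by default, giving the
strong dominance structure typical of phototrophic biofilms). Selection
regimes reweight the metacommunity with a Gaussian environmental filter
$\exp(-(t_i - o)^2 / 2\sigma^2)$ on a niche trait $t$ evolved by Brownian
motion along the tree: one shared optimum for homogeneous selection,
block-specific optima at least 4σ apart for variable selection. Per-sample
log-normal abundance noise (`sample_noise_sdlog`, default 1) emulates
ecological drift between replicate samples; without it, deeply-sequenced
small communities share every taxon, βMNTD degenerates to zero for all
pairs, and the index is undefined.

The calibration scenario follows the sizes used throughout the tests:
60 taxa, 10 samples, depth 2000, 20 seeds, under which ≤ 10% of pairs may
exceed |βNTI| = 2 (about 2–3% observed). The selection-power scenario uses
a large regional pool (800 taxa, depth 300 per sample, σ = 0.2,
8 samples): a nearest-taxon index only responds to selection through taxa
*not* shared between samples, so power requires both a pool much larger
than per-sample richness and between-sample turnover. With small pools and
deep sequencing nearly every taxon is shared and βNTI is driven by a
handful of rare taxa — a real limitation of the index, reproduced
faithfully here. Variable selection is diagnosed on the sample pairs whose
optima differ (the generator records them); pairs within a block share
their environment and are homogeneous by construction.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomic assignment noise, spatial autocorrelation between neighbouring
samples, and phylogenetic signal violations (niche convergence is present
only to the extent Brownian motion produces it). Passing tests therefore
demonstrate correctness of the machinery and statistical calibration under
a plausible model, not robustness to every artefact of real amplicon data.

## RMT threshold selection

The co-occurrence stage computes Pearson correlations between taxon
abundance profiles (by default log10 relative abundance with zeros
replaced by 0.01 × the smallest nonzero relative abundance; a
`log_counts` transform is available for abundance data that is not
sum-constrained, and matters: closure can induce sizeable negative
between-group correlations in relative data). Taxa present in fewer than
half the samples are removed first.

For each candidate threshold $s$, entries with $|r| < s$ are zeroed and
the NNSD of the surviving matrix's eigenvalues is computed:

* numerically coincident eigenvalues are collapsed first — spacings of
  exact degeneracies are an artefact of sparsity, not of the spacing law;
* the spectrum is unfolded through a cubic smoothing spline fit to the
  empirical cumulative eigenvalue count (8 knots; more knots overfit the
  cumulative count at the 20–40 eigenvalues typical here and manufacture
  spurious small spacings), after which spacings have mean 1 within 5%;
* the spacing histogram (bins of width 0.1 on [0, 3] plus a tail bin) is
  compared by chi-square against the Poisson form $e^{-d}$ and the GOE
  Wigner surmise $(\pi d/2)e^{-\pi d^2/4}$.

The chosen $s^\*$ is the smallest threshold whose NNSD is consistent with
Poisson (chi-square p > 0.05) and remains consistent at ≥ 90% of the
larger thresholds that still yield at least 20 distinct eigenvalues; the
full scan log is always returned. Demanding consistency at literally every
larger threshold is too brittle — the chi-square p fluctuates between
adjacent thresholds on matrices of a few dozen taxa.

One caveat is documented deliberately: with exactly **two** planted
modules the thresholded spectrum is a superposition of only two repulsive
spectra, which is semi-Poisson rather than Poisson, so for a small
fraction of simulated instances no threshold passes the consistency test
and `rmt_threshold()` reports that outcome (with the scan log) instead of
forcing a choice. Module-recovery precision is therefore evaluated over
the instances where a threshold is accepted. Real microbial correlation
matrices contain many modules and sit closer to the Poisson limit.

`build_network()` keeps edges with $|r| \ge s^\*$ (or $r \ge s^\*$ for the
positive-interaction subnetwork of the kind shown in co-occurrence
figures), drops isolated taxa by default, computes degrees, and exports
Gephi-loadable GraphML with degree and taxonomy attributes.

## Ordination, PERMANOVA, and the permutation tests

* **Rarefaction** subsamples once per sample, without replacement
  (multivariate hypergeometric), to exactly the requested depth; samples
  below depth are dropped with a warning.
* **NMDS** wraps monotone-regression MDS (stress-1), with a metric start
  plus 20 random restarts (300 iterations, stress-change convergence at
  1e-7), returning the lowest-stress centred configuration.
* **PERMANOVA** uses Anderson's distance-based pseudo-F with free label
  permutation. At 5 + 5 samples the permutation floor is *not*
  1/(n_perm+1): random permutations reproduce the observed 5/5 partition
  with probability ≈ 2/252 each, and those tie with the observed F. The
  floor is reached from about 10 samples per group.
* **Mantel** correlates upper-triangle entries and permutes rows and
  columns of the second matrix simultaneously; the p-value is two-sided,
  $(1 + \#\{|r_\pi| \ge |r_{\mathrm{obs}}|\})/(1 + n_\pi)$. βNTI matrices
  enter as signed scores. Spearman is available by flag.
* **The decrease screen** runs a rank-sum test per feature against the
  reference group (exact null distribution at small tie-free sample sizes,
  normal approximation with tie correction otherwise), one-sided for
  decreases by default, with Benjamini–Hochberg correction across the
  screen. Constant features are flagged with p = 1 rather than dropped.
* **ANOVA + Tukey** uses the studentized-range HSD; the compact letter
  display assigns one letter per maximal clique of the
  "not-significantly-different" graph, so groups sharing a letter do not
  differ at the chosen level.
* All permutation p-values use the add-one estimator, so p = 0 never
  occurs, and every randomized function takes an explicit seed.

Problem sizes used by the validation suite were chosen to make the
statistical properties measurable with comfortable margins: 200
Monte-Carlo repeats for the type-I error rates (rejection within
[0.02, 0.09] at α = 0.05), 20 seeds for βNTI calibration and screen FDR,
10 planted-network seeds, 120 × 120 matrices for the spectral
discrimination checks, and 100–1000 null randomizations depending on the
role of the test (1000, matching standard practice, wherever the null
moments themselves are under test).

## Known limitations

* The stochastic fraction is not partitioned further: Raup–Crick (RCbray)
  decomposition into dispersal limitation, homogenizing dispersal and
  drift is out of scope.
* Mantel regressions are simple (two-matrix) tests; multiple-matrix
  regression (MRM) is a possible extension.
* UniFrac distances, constrained ordination (CCA/RDA), module detection
  and topological role classification (Zi–Pi) in networks are not
  implemented.
* BIOM-HDF5 binary input is not supported; count tables are delimited
  text.
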