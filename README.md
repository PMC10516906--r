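# pmena

Phylogenetic null models, RMT co-occurrence networks, and permutation
statistics for microbiome community assembly.

## What problem this addresses

When an environmental driver — light quality, in the motivating system of
phototrophic biofilms growing on illuminated stone surfaces — reshapes a
microbial community, three questions follow:

1. **Which assembly process dominates?** Deterministic selection versus
   stochastic drift is inferred from phylogenetic turnover: the
   between-community β-mean nearest taxon distance (βMNTD) compared with a
   null distribution obtained by shuffling taxon labels across the tips of
   the phylogeny. The z-score, the β-nearest taxon index
   (βNTI = (βMNTD_obs − μ_null)/σ_null), classifies each sample pair:
   βNTI < −2 homogeneous selection, βNTI > +2 variable selection,
   otherwise stochastic.
2. **Who co-occurs with whom?** A Pearson correlation network among taxa,
   with the cutoff chosen objectively by random matrix theory: the
   smallest threshold at which the eigenvalue nearest-neighbour spacing
   distribution of the thresholded matrix transitions from GOE
   (Wigner–Dyson) to Poisson statistics — the signature of random noise
   having been removed.
3. **Do profiles, processes and functions covary across treatments?**
   Mantel distance-matrix regressions, NMDS ordination on Bray–Curtis
   dissimilarity, PERMANOVA, a rank-sum screen for features decreased
   relative to a reference treatment (Benjamini–Hochberg controlled),
   one-way ANOVA with Tukey HSD letters, and the RPKM / rarefaction /
   Z-score normalizations beneath them.

The package is aimed at microbial ecologists who have a taxon count
table, a rooted phylogeny and sample metadata, and want these inference
stages as tested, seeded, scriptable R functions. A synthetic-data module
generates communities with *known* assembly regimes and planted network
modules, so every stage is validated against ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic study
shaped like the motivating design — 4 light treatments × 10 samples,
uneven sequencing depths, a 300-taxon pool under treatment-specific
selection:

```sh
Rscript analysis/01_simulate.R   # writes results/data/
Rscript analysis/02_ordination.R
Rscript analysis/03_assembly.R   # ~2 min: 780 pairs x 1000 randomizations
Rscript analysis/04_network.R
Rscript analysis/05_stats.R
```

Output of the run (abridged):

```
rarefied 40 samples to 1606 reads each
PERMANOVA: pseudo-F = 28.61  R2 = 0.705  p = 0.001 ( 999 permutations )

median betaNTI within treatments: -1.31
median betaNTI between treatments: 7.2
class fractions:
homogeneous_selection  stochastic  variable_selection
                0.047       0.379               0.573

RMT threshold s* = 0.82
nodes: 40  positive edges: 379  max degree: 19
within-module edge precision: 1

Mantel (Bray-Curtis ~ betaNTI): r = 0.675  p = 0.001
screen: 20 features flagged decreased; 20 are planted truths ( 20 planted )
ANOVA F = 33.84  p = 1.41e-10 ; letters:
 light_blue light_green   light_red light_white
        "a"         "a"         "a"         "b"
```

Reading this: treatments separate compositionally (PERMANOVA R² = 0.70);
sample pairs *within* a treatment are not under detectable selection while
pairs *between* treatments show strong variable selection (median
βNTI = 7.2 ≫ +2), exactly as planted; the RMT scan picks a threshold at
which every retained positive edge connects taxa of the same planted
module; compositional turnover tracks the assembly process (Mantel
r = 0.675); the decrease screen recovers all 20 planted reductions with no
false positives; and Tukey letters separate the reference light from the
three monochromatic treatments.

The same stages are callable directly, e.g.

```r
library(pmena)
tree <- read_tree("tree.nwk")
tab  <- read_count_table("otu_table.tsv")
res  <- beta_nti(tab, tree, n_rand = 1000, weighted = TRUE, seed = 1)
head(res)   # per pair: beta_mntd_obs, null_mean, null_sd, beta_nti, class
```

or orchestrated from one YAML config with `run_all()`, which writes every
stage's outputs plus a manifest of parameters, per-stage seeds and md5
checksums (identical config + seed ⇒ identical checksums).

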