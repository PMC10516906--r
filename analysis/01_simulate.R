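#!/usr/bin/env Rscript
# Build the synthetic study dataset: four light-treatment groups of ten
# samples each (the in-situ design this pipeline is shaped for), with
# uneven per-sample depths, a dominant clade, and known assembly regimes.
# Everything downstream (02-05) reads the files written here.

suppressMessages(library(pmena))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260929L

# 4 treatment blocks x 10 samples under variable selection: each light
# treatment imposes its own environmental optimum on a conserved niche
# trait, over a 300-taxon regional pool with log-normal dominance
tree <- simulate_tree(300, seed = seed)
set.seed(seed + 1)
depths <- round(stats::runif(40, 0.8, 1.2) * 2000)  # uneven, like real runs
scenario <- assembly_scenario("variable_selection", n_taxa = 300,
                              n_samples = 40, depth = depths,
                              selection_strength = 0.4, n_blocks = 4,
                              seed = seed + 2)
tab <- simulate_communities(tree, scenario)
groups <- paste0("light_", rep(c("white", "blue", "green", "red"), each = 10))
names(groups) <- colnames(tab)

write_count_table(tab, file.path(out, "community.tsv"))
ape::write.tree(tree, file.path(out, "tree.nwk"))
utils::write.table(data.frame(sample_id = colnames(tab), group = groups),
                   file.path(out, "metadata.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

# feature table for the decrease screen: 100 features, 20% truly reduced
# by 2 sd in the non-reference treatments
ft <- simulate_feature_table(100, groups, effect_size = 2, prop_shifted = 0.2,
                             seed = seed + 3)
utils::write.table(data.frame(feature = rownames(ft$features), ft$features,
                              check.names = FALSE),
                   file.path(out, "features.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
writeLines(ft$truth, file.path(out, "features_truth.txt"))

cat("samples:", ncol(tab), " taxa:", nrow(tab),
    " depth range:", paste(range(colSums(tab)), collapse = "-"), "\n")
cat("treatments:", paste(unique(groups), collapse = ", "), "\n")
cat("truly shifted features:", length(ft$truth), "of", nrow(ft$features), "\n")
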