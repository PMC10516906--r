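#!/usr/bin/env Rscript
# Compositional profile of the synthetic biofilm communities: rarefaction
# to even depth, Bray-Curtis dissimilarity, NMDS ordination, PERMANOVA
# across the four light treatments.

suppressMessages(library(pmena))

data_dir <- "results/data"
out <- "results/ordination"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_count_table(file.path(data_dir, "community.tsv"))
md <- read_sample_metadata(file.path(data_dir, "metadata.tsv"))
groups <- sample_groups(md, colnames(tab))

depth <- min(colSums(tab))
tab_r <- rarefy(tab, depth, seed = 101)
cat("rarefied", ncol(tab_r), "samples to", depth, "reads each\n")

bc <- bray_curtis(tab_r)
write_distance_matrix(bc, file.path(out, "bray_curtis.tsv"))

ord <- nmds(bc, k = 2, n_restarts = 20, seed = 102)
utils::write.table(data.frame(sample_id = rownames(ord$points), ord$points,
                              group = groups[rownames(ord$points)]),
                   file.path(out, "nmds_coordinates.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("NMDS stress-1:", round(ord$stress, 4), "\n")

pmv <- permanova(bc, groups, n_perm = 999, seed = 103)
cat("PERMANOVA: pseudo-F =", round(pmv$f, 2), " R2 =", round(pmv$r2, 3),
    " p =", pmv$p, "(", pmv$n_perm, "permutations )\n")
jsonlite::write_json(list(depth = depth, stress = ord$stress,
                          permanova = pmv),
                     file.path(out, "summary.json"), auto_unbox = TRUE,
                     digits = NA)
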