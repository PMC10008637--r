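#!/usr/bin/env Rscript
# Stage 4: chord distances and trees.
#
# Cavalli-Sforza/Edwards chord distances among all accessions (pairwise
# deletion of missing calls), then the NJ tree used for the reference
# clustering plus the UPGMA alternative, both exported as Newick.

library(pepperdiv)

out <- "results/tree"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gm <- read_genotypes("results/data/genotypes.csv")
dm <- distance_matrix(gm)
print(dm)
cat(sprintf("theoretical chord maximum: %.3f\n", 2 * sqrt(2) / pi))
write_phylip(dm, file.path(out, "chord_distances.phy"))

nj <- nj_tree(dm)
write_newick(nj, file.path(out, "tree_nj.nwk"))
cat(sprintf("NJ: %d tips, clamped negative branch length %.4f\n",
            length(nj$tip.label), attr(nj, "clamped")))

up <- upgma_tree(dm)
write_newick(up, file.path(out, "tree_upgma.nwk"))

## how well do the two major NJ clusters line up with the populations?
cl <- cutree(hclust(as.dist(dm$d), method = "average"), k = 2)
tab <- table(cluster = cl, pop = gm$pop)
print(tab)
cat(sprintf("cluster-population agreement: %.1f%%\n",
            100 * sum(apply(tab, 1, max)) / sum(tab)))
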