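#!/usr/bin/env Rscript
# Stage 6: principal coordinate analysis of the chord-distance matrix.

library(pepperdiv)

out <- "results/pcoa"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gm <- read_genotypes("results/data/genotypes.csv")
dm <- read_phylip("results/tree/chord_distances.phy")
pc <- pcoa(dm, n_axes = 3)
print(pc)
cat(sprintf("negative eigenvalue magnitude (non-Euclidean part): %.3f\n",
            pc$negative_magnitude))

write.csv(data.frame(id = rownames(pc$coordinates), pop = gm$pop,
                     pc$coordinates),
          file.path(out, "coordinates.csv"), row.names = FALSE)
write.csv(data.frame(axis = seq_along(pc$eigenvalues),
                     eigenvalue = pc$eigenvalues),
          file.path(out, "eigenvalues.csv"), row.names = FALSE)

## separation of the two populations along axis 1
x <- pc$coordinates[, 1]
cat(sprintf("axis-1 population means: %s\n",
            paste(sprintf("%s %.3f", names(tapply(x, gm$pop, mean)),
                          tapply(x, gm$pop, mean)), collapse = ", ")))
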