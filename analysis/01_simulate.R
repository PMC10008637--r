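#!/usr/bin/env Rscript
# Stage 1: build the synthetic study dataset.
#
# The generator emulates the structure of the pepper core collection the
# package targets: 179 diploid accessions (two diverged source pools plus a
# small admixed fraction), 27 SSR/InDel-style loci with 2-20 alleles, and
# 22 categorical + 13 numeric traits. Everything downstream (stages 02-06)
# reads the files written here, exercising the same parsers as real data.

library(pepperdiv)

seed <- 20230311
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_paperlike(seed = seed)
print(sim$gm)
print(sim$tt)
cat(sprintf("realised FST between source pools: %.3f (generator F = %.2f)\n",
            fst_estimate(sim$gm, sim$labels), sim$spec$fst))
cat(sprintf("admixed individuals: %d\n", sum(sim$admixed)))

write_genotypes(sim$gm, file.path(out, "genotypes.csv"), "delimited")
write_genotypes(sim$gm, file.path(out, "genotypes.str"), "structure")
write_traits(sim$tt, file.path(out, "traits.csv"))
write.csv(data.frame(id = accession_ids(sim$gm), pop = sim$gm$pop,
                     true_cluster = sim$labels,
                     true_q1 = sim$Q[, 1], admixed = sim$admixed),
          file.path(out, "truth.csv"), row.names = FALSE)

issues <- validate_dataset(sim$gm, sim$tt)
cat("validation issues:", nrow(issues), "\n")
if (nrow(issues)) print(issues)
cat("wrote", length(list.files(out)), "files to", out, "\n")
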