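#!/usr/bin/env Rscript
# Rank every layer level against every consensus cluster by the phi
# coefficient (Pearson correlation of the 0/1 membership vectors), the way
# the integrated clusters are annotated against their input subtypes.

library(cocaclust)

layers <- read_layers("results/cohort/layers.tsv")
lab <- read.delim("results/coca/labels.tsv")
cluster_labels <- setNames(as.character(lab$label), lab$sample)

assoc <- membership_phi(cluster_labels, layers, na_policy = "zero")
dir.create("results/association", showWarnings = FALSE, recursive = TRUE)
write.table(assoc, "results/association/phi_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("top level per consensus cluster:\n")
print(assoc[assoc$rank == 1,
            c("cluster", "layer", "level", "phi")], row.names = FALSE)
cat("top five for the first cluster:\n")
print(assoc[assoc$cluster == sort(unique(assoc$cluster))[1] &
              assoc$rank <= 5,
            c("layer", "level", "phi", "rank")], row.names = FALSE)
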