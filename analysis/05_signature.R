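#!/usr/bin/env Rscript
# Derive the miRNA signature discriminating the two consensus clusters that
# split the largest subtype: Wilcoxon rank-sum per feature, BH adjustment,
# pass at adjusted p < 0.01 and |log2 fold-change| > 1; then couple the
# signature to the mRNA level by best absolute Spearman correlation.

library(cocaclust)

cohort <- generate_cohort(default_cohort_spec(seed = 1L))
lab <- read.delim("results/coca/labels.tsv")
cluster_labels <- setNames(as.character(lab$label), lab$sample)

## the two clusters holding most of the split subtype's samples
pam <- cohort$layers$pam50$labels
luma <- names(pam)[!is.na(pam) & pam == "LumA"]
luma <- intersect(luma, names(cluster_labels))
tab <- sort(table(cluster_labels[luma]), decreasing = TRUE)
cl <- names(tab)[1:2]
g1 <- luma[cluster_labels[luma] == cl[1]]
g2 <- luma[cluster_labels[luma] == cl[2]]
cat("comparing", length(g1), "vs", length(g2),
    "subtype samples in consensus clusters", cl[1], "and", cl[2], "\n")

de <- diffexp_two_group(cohort$expr$mirna, g1, g2,
                        p_thresh = 0.01, fc_thresh = 1)
dir.create("results/signature", showWarnings = FALSE, recursive = TRUE)
write_labels(setNames(rep(cl, c(length(g1), length(g2))), c(g1, g2)),
             "results/signature/comparison_groups.tsv")
write.table(de, "results/signature/diffexp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- de$feature[de$pass]
writeLines(sig, "results/signature/signature.txt")
cat("signature size:", length(sig),
    "(planted features recovered:",
    sum(sig %in% cohort$signature), "of", length(cohort$signature), ")\n")

## genes tracking the signature (|rho| > 0.4 against the mRNA panel)
flt <- spearman_filter(cohort$expr$mirna[sig, , drop = FALSE],
                       cohort$expr$mrna, threshold = 0.4)
write.table(flt, "results/signature/mrna_correlates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mRNA features with |rho| > 0.4 to a signature miRNA:",
    sum(flt$retained), "of", nrow(flt), "\n")
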