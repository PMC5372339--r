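#!/usr/bin/env Rscript
# Validate the derived signature: cluster the split subtype's samples on the
# signature features (Pearson correlation, complete linkage, two groups) and
# compare outcomes by Kaplan-Meier curves, the log-rank test and a Cox
# proportional-hazards fit.

library(cocaclust)

cohort <- generate_cohort(default_cohort_spec(seed = 1L))
sig <- readLines("results/signature/signature.txt")

# the split subtype's samples in the two consensus clusters compared when
# the signature was derived
grp <- read.delim("results/signature/comparison_groups.tsv")
luma <- grp$sample

sp <- split_by_signature(cohort$expr$mirna[, luma, drop = FALSE], sig, k = 2)
st <- cohort$survival[cohort$survival$sample %in% names(sp$groups), ]
st$group <- sp$groups[st$sample]
st <- survival_table(st)

dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)
write_labels(sp$groups, "results/survival/groups.tsv")
write.table(km_estimate(st), "results/survival/km_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

lr <- logrank_test(st)
cx <- cox_hr(st)
cat("signature split:", sum(sp$groups == 1), "vs", sum(sp$groups == 2),
    "samples\n")
cat(sprintf("log-rank chi-squared %.2f (df %d), p = %.4g\n",
            lr$chisq, lr$df, lr$p))
cat(sprintf("Cox HR %.2f (95%% CI %.2f-%.2f)\n", cx$hr, cx$ci[1], cx$ci[2]))
writeLines(sprintf(c("logrank_p\t%g", "hr\t%g", "hr_lower\t%g",
                     "hr_upper\t%g"),
                   c(lr$p, cx$hr, cx$ci[1], cx$ci[2])),
           "results/survival/report.tsv")
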