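#!/usr/bin/env Rscript
# Simulate the default multi-level cohort: 420 tumors, six latent groups
# (five subtype-like groups, with the largest split in two by the miRNA
# level), seven classification layers with noise and missingness, expression
# matrices, per-arm copy-number complexity scores and survival times.
# Writes the cohort as the delimited-text formats the pipeline reads.

library(cocaclust)

seed <- 1L
out <- "results/cohort"

spec <- default_cohort_spec(seed = seed)
cohort <- generate_cohort(spec)
write_cohort(cohort, out)

n_layers <- sapply(cohort$layers, function(l) sum(!is.na(l$labels)))
cat("Simulated", spec$n_samples, "samples;",
    "latent group sizes:\n")
print(table(cohort$latent))
cat("classified per layer:\n")
print(n_layers)
cat("samples with <2 observed layers:",
    sum(rowSums(sapply(cohort$layers,
                       function(l) !is.na(l$labels))) < 2), "\n")
cat("planted signature:", length(cohort$signature), "miRNA features\n")
cat("written to", out, "\n")
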