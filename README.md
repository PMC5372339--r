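# cocaclust

Multi-level "cluster-of-clusters" (COCA) integration of tumor
classifications, for cohorts — like multi-omic breast cancer studies — where
each sample carries categorical labels from several molecular levels (mRNA
subtype, protein subtype, copy-number complexity group, miRNA cluster,
metabolic cluster, combined-platform clusters), each level missing for a
different subset of patients.

The package provides the whole chain as tested R functions:

* **single-level classifiers** — nearest-centroid subtyping with ER-weighted
  cohort re-centering and Spearman correlation, nearest shrunken centroids
  (soft-thresholded standardized centroid differences, discriminant with
  class priors), copy-number complexity grouping (0 / 1 / ≥2 arms with score
  ≥ 0.5), recursive partitioning of expression (PART: per-node dendrogram +
  gap statistic, leaves at different heights), metabolic spectrum
  preprocessing (1.40–4.70 ppm minus five lipid windows, mean normalization)
  and flat hierarchical cuts;
* **consensus integration** — one-hot membership encoding with a
  two-observed-layers filter, the missingness-normalized Manhattan distance

  d(i,j) = 2 · (# shared layers with different labels) / (# shared layers),

  resampled consensus clustering (Ward linkage), and selection of the number
  of clusters by average silhouette width (consensus-CDF area reported as
  supporting criterion);
* **association** — phi coefficient (Pearson correlation of 0/1 membership
  vectors) ranking every input level against every consensus cluster, plus
  chi-squared tests against clinical variables with Bonferroni correction;
* **signature derivation** — per-feature Wilcoxon/t tests with BH adjustment
  (pass at adjusted p < 0.01 and |log2FC| > 1), Spearman filtering of
  correlated genes (|rho| > 0.4), Fisher-exact gene-set enrichment;
* **survival validation** — signature-based two-group split (Pearson
  distance, complete linkage), Kaplan–Meier with Greenwood bands, log-rank
  (optionally stratified), Cox hazard ratios (Efron ties);
* **a synthetic cohort generator** — a 420-sample, six-latent-group cohort
  (five subtype-like groups, the largest split in two by one driving layer,
  with a planted 71-feature signature and a twofold survival hazard) that
  gives every stage a ground truth.

See `vignettes/integrated-subtyping.Rmd` for the model, parameter defaults
and design rationale.

## Worked example

The `analysis/` scripts run the full workflow on the synthetic cohort, each
writing its tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohort -> results/cohort/
Rscript analysis/02_layer_classify.R # per-layer classifiers
Rscript analysis/03_coca.R           # consensus integration
Rscript analysis/04_associate.R      # phi ranking
Rscript analysis/05_signature.R      # discriminating signature
Rscript analysis/06_survival.R       # outcome comparison
```

`03_coca.R` prints the silhouette profile and the selected number of
clusters:

```
samples retained with >= 2 layers: 420 (dropped: 0 )
Average silhouette by K:
    2     3     4     5     6     7     8     9    10
0.323 0.422 0.493 0.563 0.604 0.602 0.556 0.545 0.480
Chosen K = 6
ARI against the latent six-group truth: 0.934
```

The silhouette has its maximum at K = 6: the integration recovers the five
subtype-like groups *and* the planted split of the largest one — the
structure no single layer shows on its own (adjusted Rand index 0.93 against
the latent truth).

`04_associate.R` ranks each input level against each consensus cluster by
phi; the first cluster is anchored by the combined-platform and mRNA levels:

```
    layer   level       phi rank
 paradigm      p3 0.7516844    1
 intclust     ic3 0.7370415    2
    pam50    LumA 0.5892596    3
    mirna      c1 0.5867429    4
     rppa Luminal 0.4840496    5
```

`05_signature.R` compares the subtype's samples across the two consensus
clusters that split it (86 vs 59 samples) and recovers the planted
signature exactly:

```
signature size: 71 (planted features recovered: 71 of 71 )
```

`06_survival.R` re-splits those samples on the derived signature and
compares outcomes:

```
signature split: 87 vs 58 samples
log-rank chi-squared 13.97 (df 1), p = 0.0001854
Cox HR 2.16 (95% CI 1.43-3.26)
```

consistent with the planted twofold hazard difference between the two
halves of the split subtype.

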