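# Membership encoding, normalized Manhattan distance, consensus clustering,
# silhouette selection.

test_that("membership encoding one-hots observed layers and drops sparse samples", {
  labs <- list(
    a = c(s1 = "A", s2 = "B", s3 = "A", s4 = NA),
    b = c(s1 = "X", s2 = "X", s3 = NA, s4 = NA),
    c = c(s1 = "P", s2 = "Q", s3 = "Q", s4 = "P"))
  m <- build_membership(as_layers(labs))
  expect_setequal(m$dropped, "s4")  # observed on one layer only
  expect_equal(nrow(m$indicator), 3)
  expect_equal(unname(m$indicator["s1", c("a.A", "a.B")]), c(1, 0))
  expect_true(all(is.na(m$indicator["s3", c("b.X")])))
  expect_equal(rowSums(m$observed), c(s1 = 3, s2 = 3, s3 = 2))
})

test_that("duplicate sample identifiers are rejected", {
  expect_error(classification_layer("a", stats::setNames(c("A", "B"),
                                                         c("s1", "s1"))),
               "unique")
})

test_that("normalized Manhattan distance: agreement 0, full disagreement 2", {
  labs <- list(
    a = c(s1 = "A", s2 = "A", s3 = "B"),
    b = c(s1 = "X", s2 = "X", s3 = "Y"),
    c = c(s1 = "P", s2 = "P", s3 = "Q"))
  d <- normalized_manhattan(build_membership(as_layers(labs)))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  expect_equal(diag(d), stats::setNames(rep(0, 3), c("s1", "s2", "s3")))
})

test_that("normalized Manhattan matches the brute-force loop on random fixtures", {
  for (seed in 1:100) {
    labs <- random_layer_fixture(n = 12, n_layers = 3, seed = seed)
    # keep samples with >= 2 observed layers so none are dropped
    nobs <- Reduce(`+`, lapply(labs, function(l) !is.na(l)))
    keep <- names(nobs)[nobs >= 2]
    labs <- lapply(labs, function(l) l[keep])
    if (length(keep) < 3) next
    d <- suppressWarnings(normalized_manhattan(build_membership(as_layers(labs))))
    o <- suppressWarnings(oracle_manhattan(labs))
    expect_lt(max(abs(d - o[rownames(d), colnames(d)])), 1e-10)
  }
})

test_that("silhouette widths match hand expansion and reference implementation", {
  # two tight clusters at distance 10
  d <- matrix(10, 6, 6); d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  s <- silhouette_widths(rep(c(1, 2), each = 3), d)
  expect_equal(s$average, 1)

  # all pairwise distances equal -> 0
  d2 <- matrix(1, 6, 6); diag(d2) <- 0
  expect_equal(silhouette_widths(rep(c(1, 2), each = 3), d2)$average, 0)

  # 8-point fixture vs the direct a/b oracle and the cluster package
  set.seed(4)
  x <- matrix(rnorm(16), 8, 2)
  d3 <- as.matrix(dist(x))
  lab <- c(1, 1, 1, 2, 2, 3, 3, 3)
  s3 <- silhouette_widths(lab, d3)
  expect_equal(s3$widths, oracle_silhouette(lab, d3), tolerance = 1e-12)
  ref <- cluster::silhouette(lab, dmatrix = d3)
  expect_equal(s3$widths, unname(ref[, "sil_width"]), tolerance = 1e-12)

  expect_error(silhouette_widths(rep(1, 6), d), "two clusters")
})

test_that("consensus entries are co-membership indicators when the full data is used", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 60, seed = 10))
  m <- build_membership(coh$layers)
  cons <- consensus_cluster(m, k_range = 2:4, reps = 5, subsample_frac = 1,
                            seed = 2)
  d <- normalized_manhattan(m)
  for (k in 2:4) {
    cc <- cons$consensus[[as.character(k)]]
    expect_true(all(cc %in% c(0, 1)))
    full <- stats::cutree(stats::hclust(stats::as.dist(d), "ward.D2"), k)
    expect_equal(unname(cc), unname(outer(full, full, "==") * 1))
  }
})

test_that("consensus matrices are symmetric with unit diagonal in [0, 1]", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 80, seed = 11))
  m <- build_membership(coh$layers)
  cons <- suppressWarnings(consensus_cluster(m, k_range = 2:6, reps = 30,
                                             subsample_frac = 0.8, seed = 3))
  for (cc in cons$consensus) {
    expect_equal(cc, t(cc))
    expect_equal(unname(diag(cc)), rep(1, nrow(cc)))
    expect_true(all(cc >= 0 & cc <= 1))
  }
  # reproducible for a fixed seed
  cons2 <- suppressWarnings(consensus_cluster(m, k_range = 2:6, reps = 30,
                                              subsample_frac = 0.8, seed = 3))
  expect_identical(cons$chosen_k, cons2$chosen_k)
  expect_identical(cons$consensus, cons2$consensus)
})

test_that("sample order does not change the clustering (up to renaming)", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 70, seed = 13))
  m1 <- build_membership(coh$layers)
  perm <- sample(length(coh$samples))
  layers_p <- lapply(coh$layers, function(l)
    classification_layer(l$name, l$labels[perm], levels = l$levels))
  m2 <- build_membership(layers_p)
  d1 <- normalized_manhattan(m1)
  d2 <- normalized_manhattan(m2)
  # the distance and encoding are exactly permutation-equivariant
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
  expect_equal(m2$indicator[rownames(m1$indicator), colnames(m1$indicator)],
               m1$indicator)
  # dendrogram tie-breaking depends on input order, so the final partitions
  # agree up to tie-induced reassignments
  c1 <- suppressWarnings(consensus_cluster(m1, k_range = 2:6, reps = 40, seed = 5))
  c2 <- suppressWarnings(consensus_cluster(m2, k_range = 2:6, reps = 40, seed = 5))
  expect_equal(c1$chosen_k, c2$chosen_k)
  expect_gte(ari(c1$chosen_labels[coh$samples],
                 c2$chosen_labels[coh$samples]), 0.9)
})
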