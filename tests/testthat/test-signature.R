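# Differential expression, correlation filtering, enrichment.

test_that("identical groups give no passing features and adjusted p of 1", {
  set.seed(1)
  x <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:20)))
  de <- diffexp_two_group(x, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(sum(de$pass), 0)
  # duplicated columns: groups literally identical feature-wise
  x2 <- cbind(x[, 1:10], x[, 1:10])
  colnames(x2) <- paste0("s", 1:20)
  de2 <- diffexp_two_group(x2, paste0("s", 1:10), paste0("s", 11:20))
  expect_true(all(de2$p_adj == 1))
})

test_that("Wilcoxon p-values match exact enumeration for small groups", {
  set.seed(2)
  for (i in 1:100) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- rnorm(n1); b <- rnorm(n2)  # continuous: no ties
    p_pkg <- stats::wilcox.test(a, b)$p.value
    expect_equal(p_pkg, oracle_wilcox_p(a, b), tolerance = 1e-10)
  }
  # and through diffexp_two_group
  x <- rbind(f1 = c(rnorm(5), rnorm(5) + 10), f2 = rnorm(10))
  colnames(x) <- paste0("s", 1:10)
  de <- diffexp_two_group(x, paste0("s", 1:5), paste0("s", 6:10),
                          p_thresh = 0.05, fc_thresh = NULL)
  expect_equal(de$p[1], oracle_wilcox_p(x[1, 1:5], x[1, 6:10]),
               tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  set.seed(3)
  for (i in 1:100) {
    p <- runif(sample(5:40, 1))^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  # monotone in raw-p order
  p <- runif(50)
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj[order(p)]) > -1e-12))
  expect_true(all(adj >= p))
})

test_that("swapping groups negates fold-changes and keeps p-values", {
  set.seed(4)
  x <- matrix(rnorm(30 * 16), 30, 16,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:16)))
  g1 <- paste0("s", 1:8); g2 <- paste0("s", 9:16)
  d12 <- diffexp_two_group(x, g1, g2)
  d21 <- diffexp_two_group(x, g2, g1)
  expect_equal(d12$log2fc, -d21$log2fc)
  expect_equal(d12$p, d21$p)
})

test_that("planted signature features are recovered with few false positives", {
  recovered <- fp <- numeric(0)
  for (sd in c(21, 22, 23)) {
    coh <- generate_cohort(default_cohort_spec(seed = sd))
    g1 <- names(coh$latent)[coh$latent == "lumA.1"]
    g2 <- names(coh$latent)[coh$latent == "lumA.2"]
    de <- diffexp_two_group(coh$expr$mirna, g1, g2,
                            p_thresh = 0.01, fc_thresh = 1)
    planted <- de$feature %in% coh$signature
    recovered <- c(recovered, sum(de$pass & planted) / sum(planted))
    fp <- c(fp, sum(de$pass & !planted) / sum(!planted))
  }
  expect_gte(stats::median(recovered), 60 / 71)
  expect_lte(stats::median(fp), 0.01)
})

test_that("one-vs-rest testing flags each planted cluster's markers", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 200, seed = 6))
  truth <- coh$expr_truth$mirna
  res <- diffexp_one_vs_rest(coh$expr$mirna, truth, p_thresh = 0.05)
  expect_setequal(names(res), sort(unique(truth)))
  for (cl in names(res))
    expect_gt(sum(res[[cl]]$p_adj < 0.05), 50)
  # shuffled labels: essentially nothing passes
  set.seed(7)
  shuf <- stats::setNames(sample(truth), names(truth))
  res0 <- diffexp_one_vs_rest(coh$expr$mirna, shuf, p_thresh = 0.05)
  expect_lte(max(vapply(res0, function(r) sum(r$p_adj < 0.05), 1)), 2)
})

test_that("Spearman filter retains monotone partners and matches hand ranks", {
  set.seed(8)
  n <- 40
  f <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("mirA", "mirB"), paste0("s", 1:n)))
  genes <- rbind(gene1 = exp(f["mirA", ]),        # monotone transform
                 gene2 = rnorm(n))                # independent
  colnames(genes) <- colnames(f)
  out <- spearman_filter(f, genes, threshold = 0.4)
  expect_true(out$retained[out$gene == "gene1"])
  expect_equal(out$rho[out$gene == "gene1"], 1)
  expect_equal(out$feature[out$gene == "gene1"], "mirA")

  # 6-sample fixture with ties vs hand-ranked computation
  fv <- matrix(c(1, 2, 2, 3, 4, 5), 1, dimnames = list("m", paste0("t", 1:6)))
  gv <- matrix(c(2, 1, 4, 4, 6, 8), 1, dimnames = list("g", paste0("t", 1:6)))
  out2 <- spearman_filter(fv, gv, threshold = 0)
  expect_equal(out2$rho, oracle_spearman(fv[1, ], gv[1, ]), tolerance = 1e-12)

  expect_error(spearman_filter(f[, 1:3, drop = FALSE],
                               genes[, 1:3, drop = FALSE]), "5 shared")
  expect_error(spearman_filter(f, genes[, integer(0), drop = FALSE]),
               "no shared")
})

test_that("independent genes are rarely retained at threshold 0.4", {
  set.seed(9)
  n <- 100
  f <- matrix(rnorm(n), 1, n, dimnames = list("m", paste0("s", 1:n)))
  genes <- matrix(rnorm(500 * n), 500, n,
                  dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  out <- spearman_filter(f, genes, threshold = 0.4)
  expect_lt(mean(out$retained), 0.01)
})

test_that("Fisher enrichment matches hypergeometric summation and BH across sets", {
  # direct 2x2 check: (8,2; 10,80)
  p_pkg <- stats::fisher.test(matrix(c(8, 2, 10, 80), 2, byrow = TRUE),
                              alternative = "greater")$p.value
  expect_equal(p_pkg, oracle_fisher_greater(8, 2, 10, 80), tolerance = 1e-12)

  set.seed(10)
  for (i in 1:100) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:20, 1); d <- sample(5:50, 1)
    if (a + b == 0 || a + c_ == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                                alternative = "greater")$p.value
    expect_equal(p_pkg, oracle_fisher_greater(a, b, c_, d), tolerance = 1e-10)
  }

  # hits = one full set; the other (disjoint) set gets p = 1
  sets <- list(on = paste0("g", 1:10), off = paste0("h", 1:10))
  res <- geneset_enrichment(paste0("g", 1:10), c(sets$on, sets$off), sets)
  expect_lt(res$p[res$set == "on"], 1e-4)
  expect_equal(res$p[res$set == "off"], 1)
  expect_error(geneset_enrichment("nope", c(sets$on, sets$off), sets), "nope")
})

test_that("target-table intersection returns matching pairs only", {
  tt <- data.frame(feature = c("m1", "m1", "m2", "m3"),
                   target = c("P1", "P2", "P1", "P3"))
  out <- target_overlap(c("m1", "m2"), c("P1"), tt)
  expect_equal(nrow(out), 2)
  expect_true(all(out$target == "P1"))
})
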