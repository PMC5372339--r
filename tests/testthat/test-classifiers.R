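# Centroid subtyping, reference normalization, NSC, CAAI grouping.

toy_model <- function(genes = paste0("g", 1:10), k = 5, seed = 1) {
  set.seed(seed)
  cents <- matrix(rnorm(length(genes) * k), length(genes), k,
                  dimnames = list(genes, paste0("class", seq_len(k))))
  centroid_model(cents, rowMeans(cents), er_neg_prop = 0.3)
}

test_that("combined centroid is the ER-weighted mean of group means", {
  model <- toy_model()
  # identical samples: combined centroid equals that vector for any c
  expr <- matrix(rep(1:10, 4), 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  er <- stats::setNames(c("neg", "neg", "pos", "pos"), colnames(expr))
  expect_equal(unname(combined_centroid(expr, er, model)), as.numeric(1:10))

  # two-gene arithmetic case: c * neg_mean + (1 - c) * pos_mean
  m2 <- centroid_model(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                       c(a = 0, b = 0), er_neg_prop = 0.25)
  e2 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("n", "p")))
  expect_equal(unname(combined_centroid(e2, c(n = "neg", p = "pos"), m2)),
               c(0.25, 0.75))

  # random cohort vs direct group-mean recomputation
  set.seed(42)
  expr <- matrix(rnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:30)))
  er <- stats::setNames(sample(c("neg", "pos"), 30, replace = TRUE),
                        colnames(expr))
  cc <- combined_centroid(expr, er, model)
  manual <- 0.3 * rowMeans(expr[, er == "neg"]) +
    0.7 * rowMeans(expr[, er == "pos"])
  expect_equal(cc, manual)

  expect_error(combined_centroid(expr, stats::setNames(rep("pos", 30),
                                                       colnames(expr)), model),
               "ER class")
})

test_that("centroid assignment picks the strongest Spearman correlation", {
  model <- toy_model()
  # cohort built so the combined centroid equals the training centroid;
  # one sample placed exactly on a reference centroid
  expr <- cbind(model$centroids, model$centroids)
  colnames(expr) <- paste0("s", 1:10)
  er <- stats::setNames(rep(c("neg", "pos"), each = 5), colnames(expr))
  res <- centroid_assign(expr, er, model)
  # combined centroid = rowMeans(centroids) in both ER groups = training
  expect_equal(unname(res$labels[1]), "class1")
  expect_equal(unname(res$correlations["s1", "class1"]), 1)

  # rank-reversed centroids: sample matching A's ranks goes to A
  cents <- cbind(A = c(1, 2, 3, 4, 5), B = c(5, 4, 3, 2, 1))
  rownames(cents) <- paste0("g", 1:5)
  m <- centroid_model(cents, stats::setNames(rep(0, 5), rownames(cents)),
                      er_neg_prop = 0.5)
  expr <- matrix(c(10, 20, 30, 40, 50, 50, 40, 30, 20, 10), 5,
                 dimnames = list(paste0("g", 1:5), c("sa", "sb")))
  er <- c(sa = "neg", sb = "pos")
  res <- centroid_assign(expr, er, m)
  expect_equal(unname(res$labels["sa"]), "A")
  expect_equal(unname(res$correlations["sa", "A"] -
                        res$correlations["sa", "B"]), 2, tolerance = 0.5)
})

test_that("assignment is invariant to a per-sample constant shift", {
  model <- toy_model()
  set.seed(3)
  expr <- model$centroids[, sample(5, 20, replace = TRUE)] +
    matrix(rnorm(10 * 20, sd = 0.3), 10)
  colnames(expr) <- paste0("s", 1:20)
  er <- stats::setNames(rep(c("neg", "pos"), 10), colnames(expr))
  r1 <- centroid_assign(expr, er, model)
  # a constant added to all genes of one sample shifts the combined centroid
  # by a constant too; Spearman correlations are unchanged
  shifted <- expr
  shifted[, 1] <- shifted[, 1] + 7
  r2 <- centroid_assign(shifted, er, model)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$correlations, r2$correlations, tolerance = 1e-12)
})

test_that("noiseless synthetic samples recover their latent subtype", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 200, seed = 8))
  cents <- attr(coh$expr$mrna, "centroids")
  model <- centroid_model(cents, rowMeans(cents), er_neg_prop = 0.3)
  res <- centroid_assign(coh$expr$mrna, coh$er_status, model)
  expect_gt(mean(res$labels == coh$latent_parent), 0.95)
})

test_that("reference normalization reproduces the target moments", {
  set.seed(9)
  x <- matrix(rnorm(200, 5, 3), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  # identity case
  out <- normalize_to_reference(x, rowMeans(x), apply(x, 1, sd))
  expect_equal(out, x)
  # z-score case
  z <- normalize_to_reference(x, rep(0, 20), rep(1, 20))
  expect_equal(unname(rowMeans(z)), rep(0, 20))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 20))
  # arbitrary reference
  rm_ <- rnorm(20); rs <- runif(20, 0.5, 2)
  y <- normalize_to_reference(x, rm_, rs)
  expect_equal(unname(rowMeans(y)), rm_, tolerance = 1e-10)
  expect_equal(unname(apply(y, 1, sd)), rs, tolerance = 1e-10)
  # flat feature
  x[1, ] <- 3
  expect_warning(y2 <- normalize_to_reference(x, rm_, rs), "zero cohort sd")
  expect_true(all(y2[1, ] == rm_[1]))
})

random_nsc <- function(seed, delta = 0.5, priors = NULL) {
  set.seed(seed)
  p <- 10; K <- 3
  nsc_model(centroids = matrix(rnorm(p * K), p, K,
                               dimnames = list(paste0("f", 1:p),
                                               paste0("k", 1:K))),
            overall = rnorm(p), s = runif(p, 0.2, 1), s0 = 0.3,
            m = runif(K, 0.1, 0.5), delta = delta, priors = priors)
}

test_that("NSC shrinkage matches the soft-threshold formula", {
  m0 <- random_nsc(1, delta = 0)
  expect_equal(nsc_shrink(m0), m0$centroids)

  m1 <- random_nsc(2, delta = 0.5)
  expect_equal(nsc_shrink(m1), oracle_nsc_shrink(m1), tolerance = 1e-12)

  # full shrinkage collapses every centroid onto the overall centroid
  se <- m1$s + m1$s0
  dmax <- max(abs(sweep(sweep(m1$centroids - m1$overall, 1, se, "/"),
                        2, m1$m, "/")))
  mfull <- random_nsc(2, delta = dmax + 1)
  expect_equal(unname(nsc_shrink(mfull)),
               matrix(mfull$overall, 10, 3), tolerance = 1e-12)
})

test_that("NSC discriminant scores and assignment follow the formula", {
  # 1-feature hand case: centroids 0 and 2, s + s0 = 1, sample at 0.9
  m <- nsc_model(centroids = matrix(c(0, 2), 1, dimnames = list("f1", c("A", "B"))),
                 overall = c(f1 = 1), s = c(f1 = 0.7), s0 = 0.3,
                 m = c(0.5, 0.5), delta = 0)
  x <- matrix(0.9, 1, 1, dimnames = list("f1", "s1"))
  res <- nsc_assign(x, m)
  expect_equal(unname(res$scores[1, ]) + 2 * log(0.5), c(0.81, 1.21))
  expect_equal(unname(res$labels), "A")

  # sample equal to a shrunken centroid goes to that class
  m2 <- random_nsc(3, delta = 0.4)
  shr <- nsc_shrink(m2)
  x2 <- matrix(shr[, 2], dimnames = list(rownames(shr), "s"))
  expect_equal(unname(nsc_assign(x2, m2)$labels), "k2")

  # unequal priors shift scores by exactly the -2 log pi term on a grid
  pri <- c(0.6, 0.3, 0.1)
  m3 <- random_nsc(4, delta = 0.2, priors = pri)
  m3u <- random_nsc(4, delta = 0.2)
  grid <- matrix(seq(-3, 3, length.out = 10), 10, 5) +
    matrix(rnorm(50, sd = 0.5), 10)
  rownames(grid) <- paste0("f", 1:10); colnames(grid) <- paste0("s", 1:5)
  su <- nsc_assign(grid, m3u)$scores
  sp <- nsc_assign(grid, m3)$scores
  shift <- sweep(sp - su, 2, -2 * log(pri) + 2 * log(1 / 3), "-")
  expect_lt(max(abs(shift)), 1e-10)

  expect_error(nsc_assign(grid[1:5, ], m3), "missing")
})

test_that("NSC with zero shrinkage and equal priors is nearest centroid in standardized space", {
  m <- random_nsc(5, delta = 0)
  set.seed(6)
  x <- matrix(rnorm(10 * 40), 10, 40,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:40)))
  lab <- nsc_assign(x, m)$labels
  se <- m$s + m$s0
  oracle <- apply(x, 2, function(v) {
    d <- vapply(seq_len(3), function(k)
      sum(((v - m$centroids[, k]) / se)^2), 1)
    paste0("k", which.min(d))
  })
  expect_identical(unname(lab), unname(oracle))
})

test_that("CAAI grouping counts arms at or above the threshold", {
  expect_equal(caai_group(c(0.1, 0.2, 0.49)), "0")
  expect_equal(caai_group(c(0.6, 0.3)), "1")
  expect_equal(caai_group(c(0.5, 0.7, 0.9)), "2")  # boundary counts
  expect_equal(caai_group(c(NA, 0.8)), "1")
  expect_true(is.na(caai_group(c(NA_real_, NA_real_))))
  # monotone: raising any score never decreases the group
  set.seed(7)
  for (i in 1:25) {
    sc <- runif(5, 0, 1.2)
    g0 <- as.integer(caai_group(sc))
    j <- sample(5, 1)
    sc[j] <- sc[j] + runif(1, 0, 1)
    expect_gte(as.integer(caai_group(sc)), g0)
  }
})

test_that("synthetic arm scores are consistent with the drawn complexity labels", {
  coh <- generate_cohort(default_cohort_spec(n_samples = 100, seed = 12))
  lab <- coh$layers$caai$labels
  derived <- apply(coh$caai_scores, 1, caai_group)
  keep <- !is.na(lab)
  expect_identical(unname(derived[keep]), unname(lab[keep]))
})
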