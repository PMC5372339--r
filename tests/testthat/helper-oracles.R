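# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately use naive loops / direct summation and
# share no code with the functions they verify.

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Normalized Manhattan distance by explicit double loop over layers/clusters.
oracle_manhattan <- function(layer_labels) {
  samples <- names(layer_labels[[1]])
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- 0; shared <- 0
    for (l in layer_labels) {
      li <- l[[samples[i]]]; lj <- l[[samples[j]]]
      if (is.na(li) || is.na(lj)) next
      shared <- shared + 1
      for (lev in unique(l[!is.na(l)])) {
        xi <- as.numeric(li == lev); xj <- as.numeric(lj == lev)
        tot <- tot + abs(xi - xj)
      }
    }
    d[i, j] <- if (shared == 0) 2 else tot / shared
  }
  d
}

# Phi coefficient via the 2x2 closed form (ad - bc) / sqrt of margins.
oracle_phi <- function(x, y) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  c_ <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  den <- sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
  if (den == 0) return(NA_real_)
  (a * d - b * c_) / den
}

# Silhouette widths by direct expansion of a(i) and b(i).
oracle_silhouette <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mine <- setdiff(which(labels == own), i)
    if (length(mine) == 0) { s[i] <- 0; next }
    a <- mean(d[i, mine])
    b <- Inf
    for (k in setdiff(unique(labels), own))
      b <- min(b, mean(d[i, labels == k]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# NSC soft-threshold shrinkage and discriminant scores, element by element.
oracle_nsc_shrink <- function(model) {
  out <- model$centroids
  for (k in seq_len(ncol(out))) for (j in seq_len(nrow(out))) {
    d <- (model$centroids[j, k] - model$overall[j]) /
      (model$m[k] * (model$s[j] + model$s0))
    dp <- sign(d) * max(abs(d) - model$delta, 0)
    out[j, k] <- model$overall[j] + model$m[k] * (model$s[j] + model$s0) * dp
  }
  out
}

oracle_nsc_scores <- function(x, shrunk, s, s0, priors) {
  vapply(seq_len(ncol(shrunk)), function(k) {
    sum((x - shrunk[, k])^2 / (s + s0)^2) - 2 * log(priors[k])
  }, 1)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration over all
# assignments of the pooled ranks (no ties assumed in callers).
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  W_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# One-sided (enrichment) Fisher exact p by hypergeometric tail summation.
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + c_; n_ <- b + d; k <- a + b
  xs <- max(0, k - n_):min(k, m)
  probs <- choose(m, xs) * choose(n_, k - xs) / choose(m + n_, k)
  sum(probs[xs >= a])
}

# Benjamini-Hochberg step-up, written as the literal procedure.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Spearman rho with average ranks, from the Pearson formula on ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Naive agglomerative clustering (complete / average linkage) by repeatedly
# merging the two nearest clusters.
oracle_agglomerate <- function(d, k, linkage = "complete") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  link <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    if (linkage == "complete") max(vals) else mean(vals)
  }
  while (length(clusters) > k) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      v <- link(clusters[[i]], clusters[[j]])
      if (v < bestv) { bestv <- v; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Small random layer fixture: n samples, a few layers with random labels and
# missingness holes.
random_layer_fixture <- function(n = 20, n_layers = 3, seed = 1) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  labs <- lapply(seq_len(n_layers), function(i) {
    k <- sample(2:4, 1)
    l <- sample(paste0("L", seq_len(k)), n, replace = TRUE)
    l[runif(n) < 0.2] <- NA
    stats::setNames(l, samples)
  })
  names(labs) <- paste0("layer", seq_len(n_layers))
  labs
}

as_layers <- function(layer_labels) {
  mapply(classification_layer, names(layer_labels), layer_labels,
         SIMPLIFY = FALSE)
}
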