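#' Silhouette widths on a precomputed distance matrix
#'
#' Standard silhouette: `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)`
#' is the mean distance to the other members of i's cluster and `b(i)` the
#' smallest mean distance to another cluster.  Members of singleton clusters
#' get width 0.
#'
#' @param labels cluster labels (length n).
#' @param dist n x n symmetric distance matrix.
#' @return list with `widths` (per sample) and `average`.
#' @export
silhouette_widths <- function(labels, dist) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(nrow(dist) == n, ncol(dist) == n)
  cl <- unique(labels)
  if (length(cl) < 2L) stop("need at least two clusters", call. = FALSE)
  widths <- numeric(n)
  mean_to <- vapply(cl, function(k) rowSums(dist[, labels == k, drop = FALSE]) /
                      sum(labels == k), numeric(n))
  for (i in seq_len(n)) {
    own <- labels[i]
    nk <- sum(labels == own)
    if (nk == 1L) { widths[i] <- 0; next }
    a <- sum(dist[i, labels == own]) / (nk - 1L)
    b <- min(mean_to[i, cl != own])
    widths[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = widths, average = mean(widths))
}

#' Consensus clustering of a membership matrix (cluster-of-clusters)
#'
#' Resampling-based consensus clustering: at each repetition a random subset
#' of samples is drawn without replacement and clustered by Ward-linkage
#' hierarchical clustering on the missingness-normalized Manhattan distance,
#' cut at each K in `k_range`.  The consensus matrix entry (i, j) is the
#' fraction of co-sampled repetitions in which i and j fell in the same
#' cluster.  Final per-K labels come from Ward clustering of `1 - consensus`;
#' K is chosen by the maximum of the average silhouette width computed on the
#' normalized Manhattan distance.  The consensus CDF area and its increments
#' (delta area) are reported as the supporting criterion.
#'
#' @param m a [build_membership()] result.
#' @param k_range candidate cluster numbers, default `2:10`.
#' @param reps resampling repetitions, default 1000.
#' @param subsample_frac fraction of samples drawn per repetition, default 0.8.
#' @param seed integer seed for the resampling.
#' @return an object of class `consensus_result`: per-K consensus matrices,
#'   labels, silhouette averages (both on the input distance and on
#'   `1 - consensus`), CDF/delta areas, and the chosen K.
#' @export
consensus_cluster <- function(m, k_range = 2:10, reps = 1000,
                              subsample_frac = 0.8, seed = 1L) {
  stopifnot(inherits(m, "membership_matrix"))
  dist <- normalized_manhattan(m)
  n <- nrow(dist)
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_field("k_range", "must lie in [2, n-1]")
  if (reps < 2L) stop_field("reps", "must be >= 2")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop_field("subsample_frac", "must be in (0, 1]")

  n_sub <- ceiling(subsample_frac * n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(reps)) {
      idx <- if (n_sub == n) seq_len(n) else sort(sample.int(n, n_sub))
      hc <- stats::hclust(stats::as.dist(dist[idx, idx]), method = "ward.D2")
      ind <- matrix(0, n, 1)
      ind[idx, 1] <- 1
      co_sample <- co_sample + tcrossprod(ind)
      for (k in k_range) {
        lab <- stats::cutree(hc, k = k)
        onehot <- matrix(0, n, k)
        onehot[cbind(idx, lab)] <- 1
        co_cluster[[as.character(k)]] <- co_cluster[[as.character(k)]] + tcrossprod(onehot)
      }
    }
  })
  never <- co_sample == 0
  if (any(never[upper.tri(never)]))
    warning(sum(never[upper.tri(never)]),
            " sample pair(s) never co-sampled; consensus imputed as 0")
  consensus <- lapply(co_cluster, function(cc) {
    cons <- cc / pmax(co_sample, 1)
    cons[never] <- 0
    diag(cons) <- 1
    dimnames(cons) <- dimnames(dist)
    cons
  })

  labels <- mapply(function(cons, k) {
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "ward.D2")
    lab <- stats::cutree(hc, k = k)
    names(lab) <- rownames(dist)
    lab
  }, consensus, k_range, SIMPLIFY = FALSE)

  sil_dist <- vapply(labels, function(lab) silhouette_widths(lab, dist)$average, 1)
  sil_cons <- mapply(function(lab, cons) silhouette_widths(lab, 1 - cons)$average,
                     labels, consensus)

  # Consensus CDF area and its increase per K (supporting criterion).
  area <- vapply(consensus, function(cons) {
    v <- cons[upper.tri(cons)]
    1 - mean(v)  # area under the empirical CDF of consensus values on [0, 1]
  }, 1)
  delta_area <- c(area[1], diff(area) / pmax(area[-length(area)], .Machine$double.eps))

  chosen <- k_range[which.max(sil_dist)]
  structure(list(k_range = k_range, consensus = consensus, labels = labels,
                 silhouette = sil_dist, silhouette_consensus = sil_cons,
                 cdf_area = area, delta_area = delta_area,
                 chosen_k = chosen, chosen_labels = labels[[as.character(chosen)]],
                 distance = dist,
                 config = list(reps = reps, subsample_frac = subsample_frac,
                               seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over", nrow(x$distance), "samples\n")
  cat("K range:", paste(range(x$k_range), collapse = "-"),
      " reps:", x$config$reps, " subsample:", x$config$subsample_frac, "\n")
  cat("Average silhouette by K:\n")
  print(round(stats::setNames(x$silhouette, x$k_range), 3))
  cat("Chosen K =", x$chosen_k, "\n")
  invisible(x)
}
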