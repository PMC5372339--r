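#' Agglomerative clustering with a flat cut
#'
#' Hierarchical clustering of the rows of `x` under the chosen distance and
#' linkage, with the dendrogram cut into exactly `k` groups.  Pearson distance
#' is `1 - r` between sample profiles.
#'
#' @param x samples x features numeric matrix, or a `dist` object.
#' @param distance `"euclidean"` or `"pearson"` (ignored if `x` is a dist).
#' @param linkage `"ward"` (Ward.D2), `"complete"` or `"average"`.
#' @param k number of clusters, `2 <= k <= n`.
#' @return integer cluster labels named by rownames.
#' @export
hcluster_cut <- function(x, distance = c("euclidean", "pearson"),
                         linkage = c("ward", "complete", "average"), k) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  d <- if (inherits(x, "dist")) x
  else if (distance == "euclidean") stats::dist(x) else dist_pearson(x)
  n <- attr(d, "Size")
  if (k > n) stop_field("k", "cannot exceed the number of samples")
  method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
  stats::cutree(stats::hclust(d, method = method), k = k)
}

within_dispersion <- function(d2, labels) {
  # Sum over clusters of (1 / 2 n_r) * sum of pairwise squared distances.
  sum(vapply(unique(labels), function(l) {
    idx <- labels == l
    sum(d2[idx, idx]) / (2 * sum(idx))
  }, 1))
}

#' Gap statistic for the number of clusters under a dendrogram cut
#'
#' Compares the log within-cluster dispersion of flat k-cuts of the data's
#' dendrogram with the same quantity on `B` reference datasets drawn
#' uniformly per feature over the observed feature ranges:
#' `gap(k) = mean_b log W_k(ref_b) - log W_k(data)`, with standard error
#' `sd_b(log W_k(ref)) * sqrt(1 + 1/B)`.  Dispersion `W_k` sums, over
#' clusters, half the mean pairwise squared distance.
#'
#' @inheritParams hcluster_cut
#' @param k_range candidate k values (may include 1).
#' @param B number of reference datasets.
#' @param seed integer seed for the reference draws.
#' @return list with `k`, `gap`, `se`, `logW`, `logW_ref` and `selected`
#'   (first k whose gap is within one reference SE of the next gap; 1 for
#'   degenerate/constant data).
#' @export
gap_statistic <- function(x, distance = c("euclidean", "pearson"),
                          linkage = c("ward", "complete", "average"),
                          k_range = 1:4, B = 50, seed = 1L) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (B < 1L) stop_field("B", "must be >= 1")
  n <- nrow(x)
  if (any(k_range < 1L) || any(k_range > n - 1L))
    stop_field("k_range", "must lie in [1, n-1]")
  k_range <- sort(k_range)

  dispersions <- function(m) {
    d <- if (distance == "euclidean") stats::dist(m) else dist_pearson(m)
    d2 <- as.matrix(d)^2
    method <- c(ward = "ward.D2", complete = "complete", average = "average")[linkage]
    hc <- stats::hclust(stats::as.dist(sqrt(d2)), method = method)
    vapply(k_range, function(k)
      within_dispersion(d2, stats::cutree(hc, k = k)), 1)
  }

  ranges <- apply(x, 2, range)
  if (all(ranges[1, ] == ranges[2, ]) ||
      (distance == "pearson" && any(apply(x, 1, stats::sd) == 0)))
    return(list(k = k_range, gap = rep(NA_real_, length(k_range)),
                se = rep(NA_real_, length(k_range)), selected = 1L))

  W <- dispersions(x)
  if (any(W == 0)) W <- pmax(W, .Machine$double.eps)
  logW_ref <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ref <- apply(ranges, 2, function(r) stats::runif(n, r[1], r[2]))
      log(pmax(dispersions(ref), .Machine$double.eps))
    }, numeric(length(k_range)))
  })
  logW_ref <- matrix(logW_ref, nrow = length(k_range))
  gap <- rowMeans(logW_ref) - log(W)
  se <- apply(logW_ref, 1, stats::sd) * sqrt(1 + 1 / B)

  selected <- k_range[length(k_range)]
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { selected <- k_range[i]; break }
  }
  list(k = k_range, gap = gap, se = se, logW = log(W),
       logW_ref = rowMeans(logW_ref), selected = selected)
}

#' Configuration for recursive partitioning
#'
#' @param Kmax maximum number of children considered at each node (>= 2).
#' @param minSize minimum cluster size; a split producing a smaller child is
#'   rejected.
#' @param B reference datasets for the gap statistic.
#' @param distance,linkage see [hcluster_cut()].
#' @param seed integer seed.
#' @return object of class `part_config`.
#' @export
part_config <- function(Kmax = 4L, minSize = 41L, B = 1000L,
                        distance = c("pearson", "euclidean"),
                        linkage = c("complete", "ward", "average"),
                        seed = 1L) {
  if (Kmax < 2L) stop_field("Kmax", "must be >= 2")
  if (minSize < 1L) stop_field("minSize", "must be >= 1")
  if (B < 1L) stop_field("B", "must be >= 1")
  structure(list(Kmax = Kmax, minSize = minSize, B = B,
                 distance = match.arg(distance), linkage = match.arg(linkage),
                 seed = seed), class = "part_config")
}

#' Recursive partitioning of samples into clusters at different heights
#'
#' Recursively splits the samples: at each node a dendrogram is built on the
#' node's samples and the gap statistic picks an optimal k in `1..Kmax`.  The
#' node becomes a leaf when k = 1 or when any prospective child would fall
#' below `minSize` samples.  Otherwise the procedure recurses into each
#' child.  Because nodes are split independently, leaf clusters may
#' correspond to dendrogram cuts at different heights.
#'
#' @param x samples x features matrix (e.g. miRNA expression, samples in
#'   rows).
#' @param config a [part_config()].
#' @return integer leaf labels (1, 2, ... in discovery order) named by sample.
#' @export
part_cluster <- function(x, config = part_config()) {
  stopifnot(inherits(config, "part_config"))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  labels <- stats::setNames(rep(NA_integer_, nrow(x)), rownames(x))
  next_leaf <- 0L
  node_seed <- 0L

  recurse <- function(idx) {
    node_seed <<- node_seed + 1L
    if (length(idx) <= 2L * config$minSize || length(idx) <= 2L) {
      next_leaf <<- next_leaf + 1L
      labels[idx] <<- next_leaf
      return(invisible())
    }
    kmax <- min(config$Kmax, length(idx) - 1L)
    gs <- gap_statistic(x[idx, , drop = FALSE], distance = config$distance,
                        linkage = config$linkage, k_range = 1:kmax,
                        B = config$B,
                        seed = child_seed(config$seed, node_seed))
    k <- gs$selected
    accept <- FALSE
    if (k > 1L) {
      children <- hcluster_cut(x[idx, , drop = FALSE],
                               distance = config$distance,
                               linkage = config$linkage, k = k)
      accept <- min(table(children)) >= config$minSize
    }
    if (!accept) {
      next_leaf <<- next_leaf + 1L
      labels[idx] <<- next_leaf
    } else {
      for (ch in seq_len(k)) recurse(idx[children == ch])
    }
    invisible()
  }
  recurse(rownames(x))
  labels
}
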