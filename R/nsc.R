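#' Nearest-shrunken-centroid model
#'
#' Parameters of the NSC classifier: class centroids, overall centroid,
#' per-feature pooled within-class standard deviations `s_j`, fudge constant
#' `s0`, class-size factors `m_k`, shrinkage threshold `Delta` and class
#' priors.
#'
#' @param centroids features x classes matrix of class centroids.
#' @param overall per-feature overall centroid.
#' @param s per-feature pooled within-class sd (>= 0).
#' @param s0 fudge constant added to every `s_j` (typically the median of
#'   `s`).
#' @param m per-class size factors, usually `sqrt(1/n_k - 1/n)`.
#' @param delta shrinkage threshold, >= 0.  Default 0 (no shrinkage: plain
#'   nearest centroid in standardized space).
#' @param priors class priors, default uniform.
#' @return object of class `nsc_model`.
#' @export
nsc_model <- function(centroids, overall, s, s0 = stats::median(s), m,
                      delta = 0, priors = NULL) {
  K <- ncol(centroids)
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (any(s < 0)) stop_field("s", "must be >= 0")
  if (delta < 0) stop_field("delta", "must be >= 0")
  if (abs(sum(priors) - 1) > 1e-8) stop_field("priors", "must sum to 1")
  if (length(m) != K) stop_field("m", "one factor per class")
  structure(list(centroids = centroids, overall = overall, s = s, s0 = s0,
                 m = m, delta = delta, priors = priors), class = "nsc_model")
}

#' Soft-threshold shrinkage of NSC class centroids
#'
#' Standardized differences `d_kj = (xbar_kj - xbar_j) / (m_k (s_j + s0))`
#' are soft-thresholded, `d'_kj = sign(d_kj) max(|d_kj| - Delta, 0)`, and the
#' shrunken centroids reassembled as
#' `xbar'_kj = xbar_j + m_k (s_j + s0) d'_kj`.  With `Delta = 0` the original
#' centroids are returned; with `Delta >= max |d_kj|` every centroid collapses
#' onto the overall centroid.
#'
#' @param model an [nsc_model()].
#' @return features x classes matrix of shrunken centroids.
#' @export
nsc_shrink <- function(model) {
  se <- model$s + model$s0
  d <- sweep(model$centroids - model$overall, 1, se, "/")
  d <- sweep(d, 2, model$m, "/")
  dp <- sign(d) * pmax(abs(d) - model$delta, 0)
  shrunk <- model$overall + sweep(sweep(dp, 2, model$m, "*"), 1, se, "*")
  dimnames(shrunk) <- dimnames(model$centroids)
  shrunk
}

#' Discriminant-score assignment to shrunken centroids
#'
#' Discriminant score for class k:
#' `delta_k(x) = sum_j (x_j - xbar'_kj)^2 / (s_j + s0)^2 - 2 log pi_k`;
#' each sample gets the class minimizing the score.  Exact ties are broken by
#' the lowest class index and flagged.
#'
#' @param expr features x samples matrix; features must match the model.
#' @param model an [nsc_model()].
#' @return list with `labels` (named character), `scores` (samples x classes)
#'   and `tied` (logical per sample).
#' @export
nsc_assign <- function(expr, model) {
  missing <- setdiff(rownames(model$centroids), rownames(expr))
  if (length(missing))
    stop("features missing from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  expr <- expr[rownames(model$centroids), , drop = FALSE]
  shrunk <- nsc_shrink(model)
  se2 <- (model$s + model$s0)^2
  K <- ncol(shrunk)
  scores <- matrix(NA_real_, ncol(expr), K,
                   dimnames = list(colnames(expr), colnames(shrunk)))
  for (k in seq_len(K))
    scores[, k] <- colSums((expr - shrunk[, k])^2 / se2) - 2 * log(model$priors[k])
  best <- apply(scores, 1, which.min)
  tied <- apply(scores, 1, function(r) sum(r == min(r)) > 1L)
  labels <- stats::setNames(colnames(shrunk)[best], colnames(expr))
  list(labels = labels, scores = scores, tied = tied)
}

#' Group samples by count of complex-aberration arms
#'
#' Counts chromosome arms whose complex arm aberration index (CAAI) score
#' meets the threshold (score >= tau counts as an event) and groups the
#' sample as `"0"` (no event), `"1"` (one arm) or `"2"` (two or more arms).
#' Missing arm scores are ignored; if all scores are missing the label is
#' `NA`.
#'
#' @param scores numeric vector of per-arm CAAI scores (NA allowed).
#' @param tau event threshold, default 0.5.
#' @return single character label, or `NA_character_`.
#' @export
caai_group <- function(scores, tau = 0.5) {
  if (tau <= 0) stop_field("tau", "must be > 0")
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) return(NA_character_)
  n_event <- sum(scores >= tau)
  if (n_event >= 2L) "2" else as.character(n_event)
}
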