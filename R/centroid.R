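#' Centroid model for nearest-centroid subtype assignment
#'
#' Holds the reference subtype centroids (e.g. the 50-gene, 5-subtype breast
#' cancer model), the centroid of the original training cohort, and the
#' proportion `c` of ER-negative samples in that training cohort.  `c` is the
#' weight used when re-centering a new cohort (see [combined_centroid()]).
#'
#' @param centroids genes x subtypes numeric matrix.
#' @param training_centroid per-gene numeric vector (same genes).
#' @param er_neg_prop proportion of ER-negative samples in the training set,
#'   in (0, 1).
#' @return object of class `centroid_model`.
#' @export
centroid_model <- function(centroids, training_centroid, er_neg_prop) {
  if (is.null(rownames(centroids))) stop_field("centroids", "need gene rownames")
  if (!identical(rownames(centroids), names(training_centroid)))
    stop_field("training_centroid", "genes must match centroid rows")
  if (er_neg_prop <= 0 || er_neg_prop >= 1)
    stop_field("er_neg_prop", "must be in (0, 1)")
  structure(list(centroids = centroids, training_centroid = training_centroid,
                 er_neg_prop = er_neg_prop, genes = rownames(centroids)),
            class = "centroid_model")
}

#' ER-weighted combined centroid of a cohort
#'
#' The combined centroid is the weighted average of the cohort's ER-negative
#' and ER-positive mean expression vectors with weights `c` and `1 - c`,
#' where `c` is the ER-negative proportion of the model's original training
#' cohort.  Aligning this combined centroid with the training centroid removes
#' cohort-level shifts caused by a different ER composition.
#'
#' @param expr genes x samples log2 expression matrix restricted to model
#'   genes.
#' @param er_status per-sample factor/character with values `"pos"`/`"neg"`
#'   (`NA` allowed; such samples are ignored here).
#' @param model a [centroid_model()].
#' @return per-gene numeric vector.
#' @export
combined_centroid <- function(expr, er_status, model) {
  er_status <- as.character(er_status)
  if (is.null(names(er_status))) names(er_status) <- colnames(expr)
  known <- names(er_status)[!is.na(er_status)]
  neg <- intersect(known[er_status[known] == "neg"], colnames(expr))
  pos <- intersect(known[er_status[known] == "pos"], colnames(expr))
  if (length(neg) == 0L || length(pos) == 0L)
    stop("cohort lacks an ER class (need both ER-positive and ER-negative ",
         "samples); skip re-centering explicitly if intended", call. = FALSE)
  cc <- model$er_neg_prop * rowMeans(expr[, neg, drop = FALSE]) +
    (1 - model$er_neg_prop) * rowMeans(expr[, pos, drop = FALSE])
  cc
}

#' Nearest-centroid subtype assignment with cohort re-centering
#'
#' Each sample's expression vector is centered by subtracting the cohort's
#' [combined_centroid()] and adding the model's training centroid, then
#' correlated (Spearman, average ranks for ties) with each subtype centroid
#' on the genes shared between data and model.  The subtype with the largest
#' correlation is assigned.  A sample whose centered vector is constant gets
#' the label `"unassigned"`.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param er_status per-sample `"pos"`/`"neg"` (NA allowed; samples without
#'   status are centered with the combined centroid computed from
#'   status-known samples).
#' @param model a [centroid_model()].
#' @param min_coverage minimum fraction of model genes that must be present
#'   in `expr`, default 0.9.
#' @return list with `labels` (named character) and `correlations`
#'   (samples x subtypes matrix of Spearman correlations).
#' @export
centroid_assign <- function(expr, er_status, model, min_coverage = 0.9) {
  shared <- intersect(model$genes, rownames(expr))
  cov <- length(shared) / length(model$genes)
  if (cov < min_coverage)
    stop(sprintf("only %.0f%% of model genes present (minimum %.0f%%)",
                 100 * cov, 100 * min_coverage), call. = FALSE)
  expr <- expr[shared, , drop = FALSE]
  cc <- combined_centroid(expr, er_status, model)
  centered <- expr - cc + model$training_centroid[shared]
  cents <- model$centroids[shared, , drop = FALSE]
  cors <- matrix(NA_real_, ncol(expr), ncol(cents),
                 dimnames = list(colnames(expr), colnames(cents)))
  labels <- stats::setNames(rep("unassigned", ncol(expr)), colnames(expr))
  for (i in seq_len(ncol(expr))) {
    x <- centered[, i]
    if (stats::sd(x) == 0) next
    cors[i, ] <- apply(cents, 2, function(v)
      stats::cor(x, v, method = "spearman"))
    labels[i] <- colnames(cents)[which.max(cors[i, ])]
  }
  list(labels = labels, correlations = cors)
}

#' Rescale a cohort matrix to a reference mean and standard deviation
#'
#' Per feature: z-score against the cohort's own mean/sd, then scale by the
#' reference sd and shift by the reference mean, so the cohort becomes
#' comparable to the reference platform.  Features with zero cohort sd are
#' set flat to the reference mean (with a warning).
#'
#' @param expr features x samples matrix.
#' @param ref_mean,ref_sd per-feature reference moments (named by feature or
#'   in row order); `ref_sd` must be positive.
#' @return rescaled matrix.
#' @export
normalize_to_reference <- function(expr, ref_mean, ref_sd) {
  if (!is.null(names(ref_mean))) ref_mean <- ref_mean[rownames(expr)]
  if (!is.null(names(ref_sd))) ref_sd <- ref_sd[rownames(expr)]
  if (any(ref_sd <= 0)) stop_field("ref_sd", "must be > 0")
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning("zero cohort sd for ", sum(flat), " feature(s); set to ref_mean")
    sd[flat] <- 1
  }
  out <- (expr - mu) / sd * ref_sd + ref_mean
  out[flat, ] <- ref_mean[flat]
  out
}
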