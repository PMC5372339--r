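#' A single classification layer
#'
#' One molecular level's categorical label per sample.  `NA` means the sample
#' was not classified on this layer (e.g. no protein data available).
#'
#' @param name layer name, e.g. `"mirna"`.
#' @param labels named character vector (names are sample identifiers); `NA`
#'   allowed.
#' @param levels optional label vocabulary; defaults to the observed labels.
#' @return an object of class `classification_layer`.
#' @export
classification_layer <- function(name, labels, levels = NULL) {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop_field("labels", "must be named by unique sample identifiers")
  ids <- names(labels)
  labels <- as.character(labels)
  names(labels) <- ids
  obs <- sort(unique(labels[!is.na(labels)]))
  if (is.null(levels)) levels <- obs
  if (!all(obs %in% levels))
    stop_field("labels", paste("labels outside vocabulary:",
                               paste(setdiff(obs, levels), collapse = ", ")))
  structure(list(name = name, labels = labels, levels = levels),
            class = "classification_layer")
}

#' Build the one-hot membership matrix for COCA
#'
#' Encodes every observed (sample, layer) classification as 0/1 indicator
#' columns keyed `layer.cluster`.  Samples classified on fewer than
#' `min_layers` layers are dropped (the analysis keeps only tumors with at
#' least two data levels) and listed in the exclusion report.
#'
#' @param layers named list of [classification_layer()] objects covering a
#'   common sample universe (union of all layer samples).
#' @param min_layers minimum number of observed layers a sample must have.
#' @return an object of class `membership_matrix` with elements
#'   \describe{
#'     \item{indicator}{samples x indicator-columns 0/1 matrix (`NA` where the
#'       layer is unobserved for the sample)}
#'     \item{observed}{samples x layers logical matrix}
#'     \item{column_layer}{layer of each indicator column}
#'     \item{dropped}{character vector of excluded sample identifiers}
#'   }
#' @export
build_membership <- function(layers, min_layers = 2L) {
  if (length(layers) < 2L) stop("need at least 2 layers", call. = FALSE)
  if (is.null(names(layers)) || !nzchar(names(layers)[1]))
    names(layers) <- vapply(layers, `[[`, "", "name")
  samples <- unique(unlist(lapply(layers, function(l) names(l$labels))))
  observed <- vapply(layers, function(l) {
    v <- rep(FALSE, length(samples))
    names(v) <- samples
    ok <- !is.na(l$labels)
    v[names(l$labels)[ok]] <- TRUE
    v
  }, logical(length(samples)))
  rownames(observed) <- samples
  n_obs <- rowSums(observed)
  keep <- n_obs >= min_layers
  dropped <- samples[!keep]
  samples <- samples[keep]
  observed <- observed[keep, , drop = FALSE]

  blocks <- lapply(layers, function(l) {
    m <- matrix(NA_real_, length(samples), length(l$levels),
                dimnames = list(samples, paste(l$name, l$levels, sep = ".")))
    lab <- l$labels[samples[samples %in% names(l$labels)]]
    for (s in names(lab)) {
      if (!is.na(lab[[s]])) {
        m[s, ] <- 0
        m[s, paste(l$name, lab[[s]], sep = ".")] <- 1
      }
    }
    m
  })
  indicator <- do.call(cbind, blocks)
  column_layer <- rep(names(layers), vapply(layers, function(l) length(l$levels), 1L))
  structure(list(indicator = indicator, observed = observed,
                 column_layer = column_layer, dropped = dropped),
            class = "membership_matrix")
}

#' Missingness-normalized Manhattan distance between samples
#'
#' For a pair of samples the Manhattan distance over indicator columns is
#' accumulated only over the layers observed in *both* samples, and divided by
#' the number of such shared layers.  Each shared layer therefore contributes
#' 0 (same cluster) or 2 (different clusters), making layers comparable
#' regardless of their cluster count and missingness: the distance equals
#' twice the fraction of shared layers on which the two samples disagree, and
#' lies in \[0, 2\].  Pairs with no shared layer get the maximal distance 2
#' (with a warning).
#'
#' @param m a [build_membership()] result.
#' @return symmetric distance matrix (samples x samples).
#' @export
normalized_manhattan <- function(m) {
  stopifnot(inherits(m, "membership_matrix"))
  n <- nrow(m$indicator)
  samples <- rownames(m$indicator)
  layers <- colnames(m$observed)
  disagree <- matrix(0, n, n)
  for (l in layers) {
    cols <- which(m$column_layer == l)
    labs <- max.col(replace(m$indicator[, cols, drop = FALSE], is.na(m$indicator[, cols, drop = FALSE]), 0))
    obs <- m$observed[, l]
    d <- outer(labs, labs, "!=") & outer(obs, obs, "&")
    disagree <- disagree + d
  }
  shared <- tcrossprod(m$observed * 1)
  none <- shared == 0
  if (any(none[upper.tri(none)]))
    warning("sample pairs with no shared observed layer: distance set to 2")
  dist <- 2 * disagree / pmax(shared, 1)
  dist[none] <- 2
  diag(dist) <- 0
  dimnames(dist) <- list(samples, samples)
  dist
}
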