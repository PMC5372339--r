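#' Two-group differential expression with FDR control
#'
#' Per feature: a two-sided Wilcoxon rank-sum test (default) or Welch t-test
#' between the two sample groups, Benjamini-Hochberg adjustment across all
#' tested features, and the log2 fold-change defined as the difference of
#' group means on the log2 scale (`group1 - group2`).  A feature passes when
#' its adjusted p-value is below `p_thresh` and, if `fc_thresh` is set, its
#' absolute log2 fold-change exceeds `fc_thresh`.
#'
#' Features constant across both groups get p = 1.
#'
#' @param expr features x samples log2 expression matrix.
#' @param group1,group2 disjoint character vectors of sample identifiers,
#'   each of size >= 2.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param p_thresh adjusted-p threshold, default 0.01.
#' @param fc_thresh absolute log2 fold-change threshold, default 1; `NULL`
#'   disables the fold-change condition.
#' @return data frame with `feature`, `statistic`, `p`, `p_adj`, `log2fc`,
#'   `pass`.
#' @export
diffexp_two_group <- function(expr, group1, group2,
                              test = c("wilcoxon", "t"),
                              p_thresh = 0.01, fc_thresh = 1) {
  test <- match.arg(test)
  if (length(intersect(group1, group2)))
    stop("groups must be disjoint", call. = FALSE)
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  x1 <- expr[, group1, drop = FALSE]
  x2 <- expr[, group2, drop = FALSE]
  res <- t(vapply(seq_len(nrow(expr)), function(j) {
    a <- x1[j, ]; b <- x2[j, ]
    if (stats::sd(c(a, b)) == 0) return(c(NA_real_, 1))
    ht <- if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(a, b))
    else stats::t.test(a, b)
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2)))
  log2fc <- rowMeans(x1) - rowMeans(x2)
  p_adj <- stats::p.adjust(res[, 2], method = "BH")
  pass <- p_adj < p_thresh
  if (!is.null(fc_thresh)) pass <- pass & abs(log2fc) > fc_thresh
  data.frame(feature = rownames(expr), statistic = res[, 1], p = res[, 2],
             p_adj = p_adj, log2fc = unname(log2fc), pass = pass,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest differential expression per cluster
#'
#' For each cluster, tests that cluster's samples against all remaining
#' samples pooled, with BH adjustment within each comparison.  Singleton
#' clusters are skipped with a warning.
#'
#' @param expr features x samples log2 expression matrix.
#' @param labels named cluster labels covering columns of `expr`.
#' @inheritParams diffexp_two_group
#' @return named list of [diffexp_two_group()] results, one per cluster
#'   (log2fc is cluster minus rest).
#' @export
diffexp_one_vs_rest <- function(expr, labels, test = c("wilcoxon", "t"),
                                p_thresh = 0.05, fc_thresh = NULL) {
  test <- match.arg(test)
  labels <- labels[intersect(names(labels), colnames(expr))]
  if (length(unique(labels)) < 2L) stop("need >= 2 clusters", call. = FALSE)
  out <- list()
  for (cl in sort(unique(as.character(labels)))) {
    inside <- names(labels)[labels == cl]
    if (length(inside) < 2L) {
      warning("cluster '", cl, "' has fewer than 2 samples; skipped")
      next
    }
    out[[cl]] <- diffexp_two_group(expr, inside, setdiff(names(labels), inside),
                                   test = test, p_thresh = p_thresh,
                                   fc_thresh = fc_thresh)
  }
  out
}

#' Filter genes by best absolute Spearman correlation with a feature list
#'
#' A gene is retained when the largest absolute Spearman rank correlation
#' (average ranks for ties) between its expression and any of the supplied
#' features exceeds the threshold.  Used to couple a miRNA signature to the
#' genes it may regulate.
#'
#' @param feature_expr features x samples matrix (e.g. signature miRNAs).
#' @param gene_expr genes x samples matrix.
#' @param threshold absolute-rho threshold, default 0.4.
#' @return data frame `gene`, `feature` (best partner), `rho`, `retained`.
#' @export
spearman_filter <- function(feature_expr, gene_expr, threshold = 0.4) {
  shared <- intersect(colnames(feature_expr), colnames(gene_expr))
  if (length(shared) == 0L) stop("no shared samples", call. = FALSE)
  if (length(shared) < 5L) stop("need >= 5 shared samples", call. = FALSE)
  rho <- stats::cor(t(gene_expr[, shared, drop = FALSE]),
                    t(feature_expr[, shared, drop = FALSE]),
                    method = "spearman")
  best <- apply(abs(rho), 1, which.max)
  best_rho <- rho[cbind(seq_len(nrow(rho)), best)]
  data.frame(gene = rownames(gene_expr),
             feature = colnames(rho)[best],
             rho = unname(best_rho),
             retained = abs(best_rho) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher-exact gene-set enrichment
#'
#' One-sided (enrichment) Fisher exact test of the overlap between the hit
#' list and each gene set within the universe, BH-adjusted across sets.
#'
#' @param hits character vector of hit genes (must be inside `universe`).
#' @param universe character vector of all testable genes.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]);
#'   set members outside the universe are ignored.
#' @return data frame `set`, `overlap`, `set_size`, `p`, `p_adj`.
#' @export
geneset_enrichment <- function(hits, universe, gene_sets) {
  bad <- setdiff(hits, universe)
  if (length(bad))
    stop("hit genes absent from universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(lengths(gene_sets) == 0L)) stop("empty gene set", call. = FALSE)
  hits <- unique(hits)
  universe <- unique(universe)
  res <- lapply(names(gene_sets), function(s) {
    set <- intersect(gene_sets[[s]], universe)
    a <- length(intersect(hits, set))
    b <- length(setdiff(hits, set))
    c_ <- length(setdiff(set, hits))
    d <- length(universe) - a - b - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    data.frame(set = s, overlap = a, set_size = length(set), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Intersect signature features with a predicted-target table
#'
#' Generic list-intersection utility: given a two-column table of predicted
#' (feature, target) pairs, returns the pairs whose feature is in the
#' signature and whose target is in the candidate list.
#'
#' @param features character vector (e.g. signature miRNAs).
#' @param candidates character vector (e.g. differentially expressed
#'   proteins/genes).
#' @param target_table data frame with columns `feature`, `target`.
#' @return subset of `target_table`.
#' @export
target_overlap <- function(features, candidates, target_table) {
  stopifnot(all(c("feature", "target") %in% colnames(target_table)))
  target_table[target_table$feature %in% features &
                 target_table$target %in% candidates, , drop = FALSE]
}
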