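#' Phi-coefficient association of subtype levels with consensus clusters
#'
#' For every (consensus cluster, layer level) pair, membership is coded 0/1
#' and the Pearson correlation of the two binary vectors (the phi
#' coefficient) is computed.  Within each consensus cluster the levels are
#' ranked by descending phi.  Samples missing a level's layer are coded 0
#' under `na_policy = "zero"` (a sample without the layer does not belong to
#' any of its levels) or dropped pairwise under `"complete"`.
#'
#' @param cluster_labels named vector of consensus cluster labels.
#' @param layers named list of [classification_layer()] objects.
#' @param na_policy `"zero"` (default) or `"complete"`.
#' @return data frame with columns `cluster`, `layer`, `level`, `phi`, `rank`
#'   (per cluster, descending phi; `NA` phi ranks last), `n`.
#' @export
membership_phi <- function(cluster_labels, layers,
                           na_policy = c("zero", "complete")) {
  na_policy <- match.arg(na_policy)
  if (is.null(names(layers)) || !nzchar(names(layers)[1]))
    names(layers) <- vapply(layers, `[[`, "", "name")
  samples <- names(cluster_labels)
  rows <- list()
  for (cl in sort(unique(as.character(cluster_labels)))) {
    x <- as.numeric(cluster_labels == cl)
    for (ln in names(layers)) {
      l <- layers[[ln]]
      lab <- l$labels[samples]
      for (lev in l$levels) {
        if (na_policy == "zero") {
          y <- as.numeric(!is.na(lab) & lab == lev)
          xi <- x
        } else {
          keep <- !is.na(lab)
          y <- as.numeric(lab[keep] == lev)
          xi <- x[keep]
        }
        phi <- if (stats::sd(xi) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(xi, y)
        rows[[length(rows) + 1L]] <-
          data.frame(cluster = cl, layer = ln, level = lev, phi = phi,
                     n = length(y), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$rank <- stats::ave(-ifelse(is.na(out$phi), -Inf, out$phi), out$cluster,
                         FUN = function(v) rank(v, ties.method = "first"))
  out[order(out$cluster, out$rank), ]
}

#' Chi-squared association between consensus clusters and clinical variables
#'
#' Per (cluster, variable): a chi-squared test (no continuity correction by
#' default) of the 2 x V table of cluster membership against the variable's
#' categories.  P-values are Bonferroni-adjusted over the whole family of
#' tests performed in the run.  Variables with a single observed category are
#' skipped with a warning; a warning is also attached when any expected cell
#' count falls below 5.
#'
#' @param cluster_labels named vector of consensus cluster labels.
#' @param clinical data frame of categorical variables, rownames = samples.
#' @param variables columns of `clinical` to test; default all.
#' @param correct continuity correction for 2 x 2 tables, default `FALSE`.
#' @return data frame with `cluster`, `variable`, `statistic`, `df`, `p`,
#'   `p_adj` (Bonferroni), `low_expected`.
#' @export
chisq_clinical <- function(cluster_labels, clinical,
                           variables = colnames(clinical), correct = FALSE) {
  samples <- intersect(names(cluster_labels), rownames(clinical))
  rows <- list()
  warned <- character()
  for (cl in sort(unique(as.character(cluster_labels[samples])))) {
    member <- factor(cluster_labels[samples] == cl, levels = c(FALSE, TRUE))
    for (v in variables) {
      val <- clinical[samples, v]
      keep <- !is.na(val)
      if (length(unique(val[keep])) < 2L) {
        if (!v %in% warned) {
          warning("variable '", v, "' has a single observed category; skipped")
          warned <- c(warned, v)
        }
        next
      }
      tab <- table(member[keep], factor(val[keep]))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, variable = v,
                   statistic = unname(ct$statistic), df = unname(ct$parameter),
                   p = ct$p.value, low_expected = any(ct$expected < 5),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = character(), variable = character(),
                      statistic = numeric(), df = numeric(), p = numeric(),
                      low_expected = logical(), p_adj = numeric()))
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p * nrow(out), 1)
  out
}
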