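#' Specification of one synthetic classification layer
#'
#' @param name layer name.
#' @param levels layer cluster names (the layer's vocabulary).
#' @param confusion latent-groups x levels row-stochastic matrix: row g gives
#'   the probability of each layer label for a sample of latent group g.
#'   Rownames must be the latent group names.
#' @param missing_rate probability in `[0, 1)` that a sample is unclassified
#'   on this layer (independent per sample).
#' @return object of class `layer_spec`.
#' @export
layer_spec <- function(name, levels, confusion, missing_rate = 0) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop_field("missing_rate", "must be in [0, 1)")
  if (ncol(confusion) != length(levels))
    stop_field("confusion", "one column per level")
  if (any(abs(rowSums(confusion) - 1) > 1e-8))
    stop_field("confusion", "rows must sum to 1")
  if (any(confusion < 0)) stop_field("confusion", "entries must be >= 0")
  colnames(confusion) <- levels
  structure(list(name = name, levels = levels, confusion = confusion,
                 missing_rate = missing_rate), class = "layer_spec")
}

#' Confusion matrix from a deterministic latent-to-level map plus noise
#'
#' Each latent group maps to one level with probability `1 - noise`; the
#' remaining mass is spread uniformly over the other levels.
#'
#' @param map named character vector: latent group -> level.
#' @param levels layer vocabulary.
#' @param noise label-noise rate in `[0, 1)`.
#' @return row-stochastic matrix with latent groups as rows.
#' @export
confusion_from_map <- function(map, levels, noise = 0) {
  stopifnot(all(map %in% levels))
  m <- matrix(if (length(levels) > 1L) noise / (length(levels) - 1L) else 0,
              length(map), length(levels),
              dimnames = list(names(map), levels))
  m[cbind(seq_along(map), match(map, levels))] <- 1 - noise
  m / rowSums(m)
}

#' Specification of a synthetic multi-level cohort
#'
#' Defines the statistical structure the integration pipeline assumes: a
#' latent grouping of the samples (five subtype-like groups with the largest
#' one split into two halves), per-layer categorical labels generated through
#' confusion matrices with independent missingness, subtype-structured
#' expression matrices, per-arm copy-number complexity scores, a planted
#' discriminating signature separating the split halves, and group-dependent
#' exponential survival.
#'
#' @param n_samples cohort size.
#' @param latent_groups named numeric vector of latent group proportions
#'   (must sum to 1).
#' @param layers named list of [layer_spec()] objects; confusion rownames
#'   must equal `names(latent_groups)`.
#' @param split_spec list with `target` (the parent group that is split),
#'   `halves` (its two latent halves), `driving_layer`,
#'   `n_signature_features` and `effect` (mean shift in log2 units added to
#'   the signature features of the first half).
#' @param expr_specs named list (one per expression layer) of lists with
#'   `n_features`, `centroid_shift` (sd of group centroid values) and
#'   `noise_sd`; each carries a `grouping` naming either `"parent"`
#'   (five-group), `"driving"` (clusters of the driving layer) or a layer
#'   whose deterministic map keys the expression centroids.
#' @param survival_spec list with `hazards` (named per latent group, > 0) and
#'   `censoring_rate` in `[0, 1)`.
#' @param n_arms number of chromosome arms for the complexity scores.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples, latent_groups, layers, split_spec,
                        expr_specs, survival_spec, n_arms = 39L, seed = 1L) {
  if (abs(sum(latent_groups) - 1) > 1e-8)
    stop_field("latent_groups", "proportions must sum to 1")
  if (any(latent_groups <= 0)) stop_field("latent_groups", "proportions must be > 0")
  for (l in layers) {
    if (!inherits(l, "layer_spec")) stop_field("layers", "need layer_spec objects")
    if (!identical(rownames(l$confusion), names(latent_groups)))
      stop_field("layers", paste0("confusion rows of '", l$name,
                                  "' must match latent groups"))
  }
  if (!all(split_spec$halves %in% names(latent_groups)))
    stop_field("split_spec", "halves must be latent groups")
  if (!split_spec$driving_layer %in% names(layers))
    stop_field("split_spec", "driving layer not among layers")
  if (any(survival_spec$hazards <= 0)) stop_field("survival_spec", "hazards must be > 0")
  if (!all(names(latent_groups) %in% names(survival_spec$hazards)))
    stop_field("survival_spec", "need a hazard for every latent group")
  if (survival_spec$censoring_rate < 0 || survival_spec$censoring_rate >= 1)
    stop_field("survival_spec", "censoring_rate must be in [0, 1)")
  structure(list(n_samples = n_samples, latent_groups = latent_groups,
                 layers = layers, split_spec = split_spec,
                 expr_specs = expr_specs, survival_spec = survival_spec,
                 n_arms = n_arms, seed = seed),
            class = "cohort_spec")
}

#' Default synthetic cohort specification
#'
#' A 420-sample cohort with six latent groups: the five mRNA-subtype-like
#' groups at their approximate population frequencies, with the largest
#' (luminal-A-like, ~42%) split into two halves distinguished only by the
#' miRNA level — different miRNA cluster labels, a 71-feature mean shift of
#' 1.5 log2 units on the miRNA expression matrix, and a twofold survival
#' hazard.  Seven classification layers mirror the real input levels
#' (mRNA subtype, protein subtype, copy-number complexity group, miRNA
#' cluster, metabolic cluster and two combined-platform clusterings); the
#' metabolic layer is deliberately uninformative about the latent grouping.
#' Label noise is 8% on the informative layers (15% on the weakly associated
#' complexity layer) and per-layer missingness follows the real availability
#' ordering, capped at 20%.
#'
#' @param n_samples cohort size, default 420.
#' @param label_noise noise rate for the informative layers, default 0.08.
#' @param seed integer seed, default 1.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n_samples = 420L, label_noise = 0.08,
                                seed = 1L) {
  groups <- c(lumA.1 = 0.200, lumA.2 = 0.216, lumB = 0.236,
              basal = 0.120, her2 = 0.111, normal = 0.117)
  gn <- names(groups)
  map <- function(...) stats::setNames(c(...), gn)
  layers <- list(
    pam50 = layer_spec("pam50", c("LumA", "LumB", "Basal", "Her2", "Normal"),
                       confusion_from_map(map("LumA", "LumA", "LumB", "Basal",
                                              "Her2", "Normal"),
                                          c("LumA", "LumB", "Basal", "Her2", "Normal"),
                                          label_noise), 0.11),
    rppa = layer_spec("rppa", c("Luminal", "ReacI", "ReacII", "Basal", "Her2"),
                      confusion_from_map(map("ReacI", "Luminal", "Luminal",
                                             "Basal", "Her2", "ReacII"),
                                         c("Luminal", "ReacI", "ReacII", "Basal", "Her2"),
                                         label_noise), 0.20),
    caai = layer_spec("caai", c("0", "1", "2"),
                      confusion_from_map(map("0", "0", "1", "2", "2", "0"),
                                         c("0", "1", "2"), 0.15), 0.18),
    mirna = layer_spec("mirna", paste0("c", 1:4),
                       confusion_from_map(map("c2", "c1", "c1", "c3", "c3", "c4"),
                                          paste0("c", 1:4), label_noise), 0.005),
    metabolic = layer_spec("metabolic", paste0("m", 1:3),
                           matrix(1 / 3, 6, 3,
                                  dimnames = list(gn, paste0("m", 1:3))), 0.20),
    intclust = layer_spec("intclust", paste0("ic", 1:10),
                          confusion_from_map(map("ic8", "ic3", "ic1", "ic10",
                                                 "ic5", "ic4"),
                                             paste0("ic", 1:10), label_noise), 0.20),
    paradigm = layer_spec("paradigm", paste0("p", 1:7),
                          confusion_from_map(map("p4", "p3", "p1", "p2", "p5", "p6"),
                                             paste0("p", 1:7), label_noise), 0.20))
  cohort_spec(
    n_samples = n_samples,
    latent_groups = groups,
    layers = layers,
    split_spec = list(target = "lumA", halves = c("lumA.1", "lumA.2"),
                      driving_layer = "mirna", n_signature_features = 71L,
                      effect = 1.5),
    expr_specs = list(
      mirna = list(n_features = 421L, centroid_shift = 1.0, noise_sd = 0.5,
                   grouping = "driving"),
      mrna = list(n_features = 50L, centroid_shift = 1.0, noise_sd = 0.5,
                  grouping = "parent"),
      protein = list(n_features = 148L, centroid_shift = 1.0, noise_sd = 0.5,
                     grouping = "rppa")),
    survival_spec = list(
      hazards = c(lumA.1 = 0.10, lumA.2 = 0.05, lumB = 0.08, basal = 0.15,
                  her2 = 0.15, normal = 0.06),
      censoring_rate = 0.30),
    seed = seed)
}

parent_of <- function(latent, split_spec) {
  ifelse(latent %in% split_spec$halves, split_spec$target, latent)
}

# Deterministic map latent group -> level for a layer (the argmax of each
# confusion row); used to key expression centroids.
layer_map <- function(lspec) {
  lspec$levels[max.col(lspec$confusion, ties.method = "first")]
}

#' Generate a synthetic multi-level cohort
#'
#' Draws latent groups from the spec's proportions; per layer, labels from
#' the group's confusion row, then masked missing independently; expression
#' matrices as group centroid + i.i.d. Gaussian noise on the log2 scale, with
#' the planted signature shift added to the first split half on the driving
#' layer's matrix; per-arm complexity scores consistent with the drawn
#' complexity-layer labels; exponential survival with group-dependent hazard
#' and independent censoring.  Identical spec + seed give identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort` with elements `samples`,
#'   `latent` (six-group truth), `latent_parent` (five-group truth), `layers`
#'   (list of [classification_layer()]), `expr` (named list of features x
#'   samples matrices), `expr_truth` (per expression matrix, the true
#'   expression-cluster label per sample), `er_status`, `caai_scores`
#'   (samples x arms), `survival` ([survival_table()]), `signature`
#'   (planted feature names) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  gn <- names(spec$latent_groups)
  samples <- sprintf("S%03d", seq_len(n))

  latent <- with_seed(child_seed(spec$seed, 1L), {
    stats::setNames(sample(gn, n, replace = TRUE, prob = spec$latent_groups),
                    samples)
  })
  parent <- stats::setNames(parent_of(latent, spec$split_spec), samples)

  layers <- vector("list", length(spec$layers))
  names(layers) <- names(spec$layers)
  for (i in seq_along(spec$layers)) {
    ls <- spec$layers[[i]]
    lab <- with_seed(child_seed(spec$seed, 10L + i), {
      drawn <- vapply(latent, function(g)
        sample(ls$levels, 1L, prob = ls$confusion[g, ]), "")
      miss <- stats::runif(n) < ls$missing_rate
      drawn[miss] <- NA_character_
      drawn
    })
    layers[[i]] <- classification_layer(ls$name,
                                        stats::setNames(lab, samples),
                                        levels = ls$levels)
  }

  # Expression matrices: centroid per expression cluster + Gaussian noise.
  driving <- spec$split_spec$driving_layer
  expr <- list()
  expr_truth <- list()
  signature <- character()
  for (j in seq_along(spec$expr_specs)) {
    en <- names(spec$expr_specs)[j]
    es <- spec$expr_specs[[en]]
    feats <- paste0(en, "_", seq_len(es$n_features))
    grouping <- es$grouping
    if (identical(grouping, "parent")) {
      cl <- parent
    } else {
      key_layer <- if (identical(grouping, "driving")) driving else grouping
      m <- stats::setNames(layer_map(spec$layers[[key_layer]]), gn)
      cl <- stats::setNames(unname(m[latent]), samples)
      if (identical(grouping, "driving")) {
        # the split halves share a base centroid; only the planted signature
        # shift (added below) separates them in expression
        cl[latent == spec$split_spec$halves[1]] <-
          m[[spec$split_spec$halves[2]]]
      }
    }
    out <- with_seed(child_seed(spec$seed, 30L + j), {
      cls <- sort(unique(cl))
      cents <- matrix(stats::rnorm(es$n_features * length(cls),
                                   sd = es$centroid_shift),
                      es$n_features, length(cls),
                      dimnames = list(feats, cls))
      mat <- cents[, cl] + matrix(stats::rnorm(es$n_features * n,
                                               sd = es$noise_sd),
                                  es$n_features, n)
      colnames(mat) <- samples
      sig <- if (en == driving || identical(grouping, "driving")) {
        s <- sample(feats, spec$split_spec$n_signature_features)
        # mixed-sign effects: some features up in the first half, some down,
        # as in real discriminating signatures; a same-sign shift would be
        # invisible to correlation-based clustering
        sgn <- sample(c(-1, 1), length(s), replace = TRUE)
        half1 <- samples[latent == spec$split_spec$halves[1]]
        mat[s, half1] <- mat[s, half1] + spec$split_spec$effect * sgn
        s
      } else character()
      list(mat = mat, centroids = cents, sig = sig)
    })
    expr[[en]] <- out$mat
    expr_truth[[en]] <- cl
    attr(expr[[en]], "centroids") <- out$centroids
    if (length(out$sig)) {
      signature <- out$sig
      # the split makes the two halves distinct expression clusters
      expr_truth[[en]][latent == spec$split_spec$halves[1]] <-
        paste0(unique(cl[latent == spec$split_spec$halves[1]])[1], ".split")
    }
  }

  er_map <- c(basal = "neg", her2 = "neg")
  er_status <- stats::setNames(
    ifelse(latent %in% names(er_map), "neg", "pos"), samples)

  # Per-arm complexity scores consistent with the drawn complexity labels.
  caai_scores <- NULL
  if ("caai" %in% names(layers)) {
    caai_scores <- with_seed(child_seed(spec$seed, 50L), {
      lab <- layers[["caai"]]$labels
      m <- matrix(stats::runif(n * spec$n_arms, 0, 0.45), n, spec$n_arms,
                  dimnames = list(samples, paste0("arm", seq_len(spec$n_arms))))
      for (s in samples) {
        k <- switch(ifelse(is.na(lab[[s]]), "na", lab[[s]]),
                    "0" = 0L, "1" = 1L, "2" = 2L + stats::rpois(1, 1), 0L)
        if (k > 0) {
          arms <- sample(spec$n_arms, min(k, spec$n_arms))
          m[s, arms] <- stats::runif(length(arms), 0.6, 1.5)
        }
      }
      m
    })
  }

  surv <- generate_survival(latent, spec$survival_spec,
                            seed = child_seed(spec$seed, 60L))

  structure(list(samples = samples, latent = latent, latent_parent = parent,
                 layers = layers, expr = expr, expr_truth = expr_truth,
                 er_status = er_status, caai_scores = caai_scores,
                 survival = surv, signature = signature, spec = spec),
            class = "synthetic_cohort")
}

#' Generate a group-dependent exponential survival table
#'
#' Event times are exponential with the group's hazard; censoring times are
#' independent exponentials calibrated so that the expected censored fraction
#' equals `censoring_rate` (for exponential event times).  With
#' `censoring_rate = 0` every record is an event.
#'
#' @param groups named vector of group labels per sample.
#' @param survival_spec list with `hazards` (named, covering every group) and
#'   `censoring_rate`.
#' @param seed integer seed.
#' @param covariates optional data frame of extra columns (rownames =
#'   samples) carried through to the output.
#' @return a [survival_table()] with columns `sample`, `time`, `event`,
#'   `group` (+ covariates).
#' @export
generate_survival <- function(groups, survival_spec, seed = 1L,
                              covariates = NULL) {
  unknown <- setdiff(unique(as.character(groups)), names(survival_spec$hazards))
  if (length(unknown))
    stop("no hazard for group(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  q <- survival_spec$censoring_rate
  if (q < 0 || q >= 1) stop_field("censoring_rate", "must be in [0, 1)")
  h <- survival_spec$hazards[as.character(groups)]
  df <- with_seed(seed, {
    tt <- stats::rexp(length(groups), rate = h)
    if (q > 0) {
      cc <- stats::rexp(length(groups), rate = h * q / (1 - q))
      data.frame(sample = names(groups), time = pmin(tt, cc),
                 event = as.integer(tt <= cc),
                 group = as.character(groups), stringsAsFactors = FALSE)
    } else {
      data.frame(sample = names(groups), time = tt, event = 1L,
                 group = as.character(groups), stringsAsFactors = FALSE)
    }
  })
  if (!is.null(covariates)) df <- cbind(df, covariates[df$sample, , drop = FALSE])
  survival_table(df)
}

#' Write a synthetic cohort to delimited-text files
#'
#' Emits the same formats the real pipeline reads: long-format layer TSV,
#' per-layer expression TSVs, complexity-score TSV and survival TSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layers(cohort$layers, file.path(dir, "layers.tsv"))
  for (en in names(cohort$expr))
    write_matrix(cohort$expr[[en]], file.path(dir, paste0("expr_", en, ".tsv")))
  if (!is.null(cohort$caai_scores))
    write_matrix(cohort$caai_scores, file.path(dir, "caai_scores.tsv"),
                 id_col = "sample")
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_labels(cohort$latent, file.path(dir, "latent.tsv"))
  writeLines(cohort$signature, file.path(dir, "signature.txt"))
  invisible(dir)
}
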