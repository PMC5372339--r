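#' Assemble a validated pipeline configuration
#'
#' A run configuration bundles the input source, every stage's parameters and
#' the seeds all randomness flows from.  `input` is either
#' `list(type = "synthetic", ...)` (arguments passed to
#' [default_cohort_spec()]) or `list(type = "files", layers = <path>,
#' expr = <named paths>, survival = <path>)`; referenced paths are checked at
#' validation time, before any computation.
#'
#' @param input input description (see above).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed global integer seed; stage seeds are derived from it.
#' @param coca list: `min_layers`, `k_range`, `reps`, `subsample_frac`.
#' @param association list: `na_policy`.
#' @param signature list: `enabled`, `expr_layer`, `subtype_layer`,
#'   `subtype_level`, `test`, `p_thresh`, `fc_thresh`.
#' @param survival list: `enabled`, `k`.
#' @return validated config list of class `coca_config`.
#' @export
coca_config <- function(input = list(type = "synthetic"),
                        out_dir = NULL, seed = 1L,
                        coca = list(), association = list(),
                        signature = list(), survival = list()) {
  defaults <- list(
    coca = list(min_layers = 2L, k_range = 2:10, reps = 1000L,
                subsample_frac = 0.8),
    association = list(na_policy = "zero"),
    signature = list(enabled = TRUE, expr_layer = "mirna",
                     subtype_layer = "pam50", subtype_level = "LumA",
                     test = "wilcoxon", p_thresh = 0.01, fc_thresh = 1),
    survival = list(enabled = TRUE, k = 2L))
  merge <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(input = input, out_dir = out_dir, seed = as.integer(seed),
              coca = merge(defaults$coca, coca),
              association = merge(defaults$association, association),
              signature = merge(defaults$signature, signature),
              survival = merge(defaults$survival, survival))
  if (is.null(input$type) || !input$type %in% c("synthetic", "files"))
    stop_field("input$type", "must be 'synthetic' or 'files'")
  if (input$type == "files") {
    for (p in c(input$layers, unlist(input$expr), input$survival))
      if (!is.null(p) && !file.exists(p))
        stop_field("input", paste("path does not exist:", p))
    if (is.null(input$layers)) stop_field("input$layers", "required for file input")
  }
  class(cfg) <- "coca_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file.
#' @return a validated [coca_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(coca_config, y)
}

config_hash <- function(cfg) {
  # hash of the analytic configuration; the output location is not part of it
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  b <- utf8ToInt(s)
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% 4294967296)
}

#' Run the full integration pipeline
#'
#' Executes, in dependency order: input loading (or synthetic cohort
#' generation), membership encoding with the minimum-layer filter, consensus
#' clustering with silhouette-based selection of K, phi-coefficient
#' association of every layer level with every consensus cluster, derivation
#' of the signature discriminating the two consensus clusters that split the
#' configured subtype, and survival comparison of the signature-based split.
#' Every output table is written under `out_dir` (if set) together with a
#' structured log and a config snapshot carrying the config hash; a rerun
#' with the same config is byte-identical.
#'
#' @param config a [coca_config()] (or a list coercible to one).
#' @return list with elements `cohort`/`layers`, `membership`, `consensus`,
#'   `association`, `signature`, `survival`, `log`, `config`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "coca_config")) config <- do.call(coca_config, config)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  hash <- config_hash(config)

  # --- input -----------------------------------------------------------
  cohort <- NULL
  surv <- NULL
  expr <- list()
  if (config$input$type == "synthetic") {
    args <- config$input[setdiff(names(config$input), "type")]
    if (is.null(args$seed)) args$seed <- child_seed(config$seed, 100L)
    spec <- do.call(default_cohort_spec, args)
    cohort <- generate_cohort(spec)
    layers <- cohort$layers
    expr <- cohort$expr
    surv <- cohort$survival
    note("stage=input type=synthetic n=%d layers=%d", spec$n_samples,
         length(layers))
  } else {
    layers <- read_layers(config$input$layers)
    for (en in names(config$input$expr))
      expr[[en]] <- read_matrix(config$input$expr[[en]])
    if (!is.null(config$input$survival))
      surv <- read_survival(config$input$survival)
    note("stage=input type=files layers=%d", length(layers))
  }

  # --- membership + consensus -----------------------------------------
  m <- build_membership(layers, min_layers = config$coca$min_layers)
  note("stage=membership n_in=%d n_kept=%d n_dropped=%d",
       nrow(m$indicator) + length(m$dropped), nrow(m$indicator),
       length(m$dropped))
  cons <- consensus_cluster(m, k_range = config$coca$k_range,
                            reps = config$coca$reps,
                            subsample_frac = config$coca$subsample_frac,
                            seed = child_seed(config$seed, 200L))
  note("stage=coca chosen_k=%d silhouette=%.3f", cons$chosen_k,
       max(cons$silhouette))

  # --- association -----------------------------------------------------
  assoc <- membership_phi(cons$chosen_labels, layers,
                          na_policy = config$association$na_policy)
  note("stage=association pairs=%d na_policy=%s", nrow(assoc),
       config$association$na_policy)

  # --- signature -------------------------------------------------------
  sig_res <- NULL
  sig_groups <- NULL
  if (isTRUE(config$signature$enabled) &&
      config$signature$expr_layer %in% names(expr)) {
    sl <- layers[[config$signature$subtype_layer]]
    level_samples <- names(sl$labels)[!is.na(sl$labels) &
                                        sl$labels == config$signature$subtype_level]
    level_samples <- intersect(level_samples, names(cons$chosen_labels))
    tab <- sort(table(cons$chosen_labels[level_samples]), decreasing = TRUE)
    if (length(tab) >= 2L) {
      cl_pair <- names(tab)[1:2]
      g1 <- level_samples[cons$chosen_labels[level_samples] == cl_pair[1]]
      g2 <- level_samples[cons$chosen_labels[level_samples] == cl_pair[2]]
      ex <- expr[[config$signature$expr_layer]]
      g1 <- intersect(g1, colnames(ex)); g2 <- intersect(g2, colnames(ex))
      sig_res <- diffexp_two_group(ex, g1, g2, test = config$signature$test,
                                   p_thresh = config$signature$p_thresh,
                                   fc_thresh = config$signature$fc_thresh)
      sig_groups <- list(clusters = cl_pair, group1 = g1, group2 = g2)
      note("stage=signature clusters=%s/%s n1=%d n2=%d n_pass=%d",
           cl_pair[1], cl_pair[2], length(g1), length(g2), sum(sig_res$pass))
    } else {
      note("stage=signature skipped: subtype level not split across clusters")
    }
  }

  # --- survival --------------------------------------------------------
  surv_res <- NULL
  if (isTRUE(config$survival$enabled) && !is.null(surv) &&
      !is.null(sig_res) && sum(sig_res$pass) >= 2L) {
    ex <- expr[[config$signature$expr_layer]]
    keep <- c(sig_groups$group1, sig_groups$group2)
    split <- split_by_signature(ex[, keep, drop = FALSE],
                                sig_res$feature[sig_res$pass],
                                k = config$survival$k)
    st <- surv[surv$sample %in% names(split$groups), , drop = FALSE]
    st$group <- split$groups[st$sample]
    st <- survival_table(st)
    lr <- logrank_test(st)
    cx <- cox_hr(st)
    surv_res <- list(split = split, table = st, logrank = lr, cox = cx)
    note("stage=survival logrank_p=%.4g hr=%.3f", lr$p, cx$hr)
  }

  out <- list(cohort = cohort, layers = layers, membership = m,
              consensus = cons, association = assoc,
              signature = sig_res, signature_groups = sig_groups,
              survival = surv_res, log = log,
              config = config, config_hash = hash)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_labels(cons$chosen_labels, file.path(dir, "coca_labels.tsv"))
    write_matrix(cons$consensus[[as.character(cons$chosen_k)]],
                 file.path(dir, "consensus_matrix.tsv"), id_col = "sample")
    utils::write.table(assoc, file.path(dir, "association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(k = cons$k_range, silhouette = cons$silhouette,
                 cdf_area = cons$cdf_area, delta_area = cons$delta_area),
      file.path(dir, "model_selection.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(sig_res))
      utils::write.table(sig_res, file.path(dir, "signature.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    if (!is.null(surv_res)) {
      write_labels(surv_res$split$groups, file.path(dir, "survival_groups.tsv"))
      utils::write.table(km_estimate(surv_res$table),
                         file.path(dir, "km_curves.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeLines(sprintf("logrank_p\t%g\nhr\t%g\nhr_lower\t%g\nhr_upper\t%g",
                         surv_res$logrank$p, surv_res$cox$hr,
                         surv_res$cox$ci[1], surv_res$cox$ci[2]),
                 file.path(dir, "survival_report.tsv"))
    }
    writeLines(paste0("# config_hash: ", hash), file.path(dir, "run.log"))
    cat(log, file = file.path(dir, "run.log"), sep = "\n", append = TRUE)
    snap <- unclass(config)
    snap$config_hash <- hash
    yaml::write_yaml(snap, file.path(dir, "config_snapshot.yaml"))
  }
  out
}
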