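#' Read a delimited expression matrix
#'
#' Parses a TSV/CSV matrix with a header row of sample identifiers and a first
#' column of feature identifiers.  Values are log2-scale expression; the
#' missing-value token (default `NA`) is honoured.  Duplicate feature or
#' sample identifiers are rejected.
#'
#' @param path file path.
#' @param orientation `"features_by_samples"` (default) or
#'   `"samples_by_features"`; the returned matrix is always features x samples.
#' @param sep field separator, default tab.
#' @param na character vector of missing-value tokens.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_matrix <- function(path, orientation = c("features_by_samples",
                                              "samples_by_features"),
                        sep = "\t", na = c("NA", "")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE, quote = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated row identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cn <- colnames(df)[-1L]
  if (anyDuplicated(cn))
    stop("duplicated column identifiers: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!is.na(m) & is.na(suppressWarnings(array(as.numeric(m), dim(m)))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1, 1], cn[bad[1, 2]]), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "samples_by_features") m <- t(m)
  m
}

#' Write a matrix as TSV
#'
#' Inverse of [read_matrix()]: first column carries the row identifiers.
#'
#' @param m numeric matrix with dimnames.
#' @param path destination path.
#' @param id_col name for the identifier column.
#' @export
write_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read classification layers
#'
#' Accepts either long format (columns `sample`, `layer`, `label`) or wide
#' format (first column `sample`, one column per layer).  Long format is
#' canonical; wide input is normalized on read.  Missing labels (token `NA`
#' or empty) mean the sample was not classified on that layer.
#'
#' @param path TSV path.
#' @return named list of [classification_layer()] objects.
#' @export
read_layers <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                          check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  if (identical(tolower(colnames(df)[1:3]), c("sample", "layer", "label")) &&
      ncol(df) == 3L) {
    samples <- unique(df$sample)
    layers <- lapply(split(df, df$layer), function(d) {
      lab <- rep(NA_character_, length(samples))
      names(lab) <- samples
      lab[as.character(d$sample)] <- as.character(d$label)
      lab
    })
  } else {
    samples <- as.character(df[[1L]])
    if (anyDuplicated(samples))
      stop("duplicated sample identifiers in layer table", call. = FALSE)
    layers <- lapply(df[-1L], function(x) {
      lab <- as.character(x)
      names(lab) <- samples
      lab
    })
  }
  mapply(classification_layer, names(layers), layers, SIMPLIFY = FALSE)
}

#' Write classification layers as long-format TSV
#'
#' @param layers named list of [classification_layer()] objects.
#' @param path destination path.
#' @export
write_layers <- function(layers, path) {
  rows <- do.call(rbind, lapply(layers, function(l) {
    keep <- !is.na(l$labels)
    data.frame(sample = names(l$labels)[keep], layer = l$name,
               label = unname(l$labels[keep]), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-sample label vector as two-column TSV
#' @param labels named character/integer vector.
#' @param path destination path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Expected columns: `sample`, `time`, `event`, then optional `group`,
#' `stratum` and covariates.
#'
#' @param path TSV path.
#' @return data frame of class `survival_table`.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                          check.names = FALSE, stringsAsFactors = FALSE, quote = "")
  survival_table(df)
}

#' Validate a survival table
#'
#' @param df data frame with at least `sample`, `time`, `event`.
#' @return the validated data frame, classed `survival_table`.
#' @export
survival_table <- function(df) {
  for (col in c("sample", "time", "event"))
    if (!col %in% colnames(df)) stop_field(col, "column missing")
  if (any(df$time < 0, na.rm = TRUE)) stop_field("time", "must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop_field("event", "must be 0/1")
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read gene sets in GMT format
#'
#' @param path GMT path (set name, description, then member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}
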