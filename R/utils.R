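#' @keywords internal
"_PACKAGE"

# Child seeds: one global integer fans out to per-component streams by fixed
# offsets, so each cohort component is reproducible on its own.  Kept below
# .Machine$integer.max.
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483562L) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' Pearson correlation distance
#'
#' Distance between the rows of a matrix defined as one minus the Pearson
#' correlation coefficient.
#'
#' @param x numeric matrix, observations in rows.
#' @return a [stats::dist] object.
#' @export
dist_pearson <- function(x) {
  stats::as.dist(1 - stats::cor(t(x)))
}
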