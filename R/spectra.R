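#' A set of metabolic spectra
#'
#' Intensity matrix over a ppm axis, with the analysis window and the
#' lipid-region exclusion windows used before clustering.  The defaults are
#' the low-molecular-weight metabolite window 1.40-4.70 ppm minus five
#' lipid-containing intervals.
#'
#' @param ppm numeric ppm axis (any order; stored descending).
#' @param intensity samples x ppm-bins matrix of non-negative intensities.
#' @param window inclusive analysis window `c(lo, hi)` in ppm.
#' @param exclusions list of `c(lo, hi)` ppm intervals to drop (must lie
#'   within `window`).
#' @return object of class `spectrum_set`.
#' @export
spectrum_set <- function(ppm, intensity,
                         window = c(1.40, 4.70),
                         exclusions = list(c(4.27, 4.36), c(2.70, 2.88),
                                           c(2.20, 2.30), c(1.93, 2.09),
                                           c(1.50, 1.67))) {
  if (length(ppm) != ncol(intensity))
    stop_field("ppm", "length must match intensity columns")
  if (any(intensity < 0, na.rm = TRUE))
    stop_field("intensity", "must be >= 0")
  exclusions <- lapply(exclusions, function(e) sort(e))
  for (e in exclusions)
    if (e[1] < window[1] || e[2] > window[2])
      stop_field("exclusions", "must lie within the analysis window")
  ord <- order(ppm, decreasing = TRUE)
  structure(list(ppm = ppm[ord],
                 intensity = intensity[, ord, drop = FALSE],
                 window = sort(window), exclusions = exclusions),
            class = "spectrum_set")
}

#' Preprocess metabolic spectra for clustering
#'
#' Retains the ppm bins inside the analysis window but outside every
#' exclusion interval (both window ends inclusive, exclusion interiors
#' exclusive of their endpoints' complement: a bin is dropped when
#' `lo <= ppm <= hi` for any exclusion), then mean-normalizes each sample so
#' its retained intensity vector has mean 1.
#'
#' @param spectra a [spectrum_set()].
#' @return features x samples matrix (retained ppm bins as features, named by
#'   ppm value).
#' @export
preprocess_spectra <- function(spectra) {
  stopifnot(inherits(spectra, "spectrum_set"))
  ppm <- spectra$ppm
  keep <- ppm >= spectra$window[1] & ppm <= spectra$window[2]
  for (e in spectra$exclusions)
    keep <- keep & !(ppm >= e[1] & ppm <= e[2])
  if (!any(keep)) stop("no ppm bins retained after exclusions", call. = FALSE)
  m <- spectra$intensity[, keep, drop = FALSE]
  m <- m / rowMeans(m)
  out <- t(m)
  rownames(out) <- format(ppm[keep], trim = TRUE)
  out
}
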