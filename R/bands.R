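#' Select diagnostic wavebands from a full-spectrum model
#'
#' Picks the k bands with the largest absolute regression coefficients of the
#' full-spectrum model, greedily, subject to a minimum index separation so
#' that adjacent near-duplicate bands of one absorption feature are not all
#' selected. Ties in |beta| are broken toward the lower wavelength. Band
#' reduction enables cheaper multispectral instruments to reuse the
#' calibration.
#'
#' @param model a \code{\link{PLSModel}}.
#' @param k number of bands to select.
#' @param minSep minimum index separation between selected bands (default 3);
#'   0 disables the constraint.
#' @return integer band indices, sorted ascending.
#' @export
selectBands <- function(model, k, minSep = 3L) {
  beta <- model@beta
  nb <- length(beta)
  k <- as.integer(k)
  if (k < 1L || k > nb) stop("k must be between 1 and the number of bands")
  # order by |beta| descending, ties toward lower band index (lower wavelength)
  ord <- order(-abs(beta), seq_len(nb))
  chosen <- integer(0)
  for (i in ord) {
    if (minSep > 0L && length(chosen) && any(abs(chosen - i) < minSep)) next
    chosen <- c(chosen, i)
    if (length(chosen) == k) break
  }
  if (length(chosen) < k)
    stop(sprintf("only %d bands satisfy the separation constraint; lower minSep or k",
                 length(chosen)))
  sort(chosen)
}

#' Refit a calibration on a reduced band set
#'
#' Runs the same pre-treatment + PLS + segmented-CV pipeline on the selected
#' column subset; the LV count is additionally bounded by the number of
#' selected bands.
#'
#' @param X objects x bands matrix of raw spectra or a
#'   \code{\link{SpectralDataset}}.
#' @param y response vector, or (for a dataset) use \code{analyte}.
#' @param bands integer band indices from \code{\link{selectBands}}.
#' @param maxLV largest LV to evaluate (capped at \code{length(bands)}).
#' @param nSegments,seed,chain,analyte,lvTol as in
#'   \code{\link{crossValidate}}.
#' @return list with \code{model} and \code{cv}, as
#'   \code{\link{crossValidate}}; the model's wavelength slot holds the
#'   selected wavelengths.
#' @export
refitReduced <- function(X, y = NULL, bands, maxLV, nSegments = 20L, seed = 1L,
                         chain = preprocessChain(), analyte = NA_character_,
                         lvTol = 0.02) {
  wl <- NULL
  if (is(X, "SpectralDataset")) {
    wl <- wavelengths(X)
    if (is.null(y)) y <- referenceValues(X, analyte)
    X <- spectraMatrix(X)
  }
  bands <- sort(as.integer(bands))
  Xr <- X[, bands, drop = FALSE]
  out <- crossValidate(Xr, y, maxLV = min(maxLV, length(bands)),
                       nSegments = nSegments, seed = seed, chain = chain,
                       analyte = analyte, lvTol = lvTol)
  if (!is.null(wl)) out$model@wavelengths <- wl[bands]
  out$bands <- bands
  out
}
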