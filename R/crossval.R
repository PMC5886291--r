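#' Choose the number of latent variables from an RMSECV curve
#'
#' The smallest LV whose RMSECV lies within a relative tolerance of the curve
#' minimum; with tolerance 0 this is the argmin, and a flat curve gives the
#' most parsimonious model (1 LV). This operationalises "minimise the
#' prediction error while avoiding overfitting".
#'
#' @param curve numeric per-LV RMSECV values (index = LV).
#' @param tol relative tolerance (default 0.02).
#' @return chosen LV (integer).
#' @examples
#' selectLV(c(5, 3, 2.9, 2.88, 3.1))  # 3
#' @export
selectLV <- function(curve, tol = 0.02) {
  if (!length(curve)) stop("empty RMSECV curve")
  as.integer(which(curve <= (1 + tol) * min(curve))[1])
}

.makeSegments <- function(n, nSegments, seed) {
  withSeed(seed, {
    # near-equal random segments: permute objects, deal them round-robin
    perm <- sample.int(n)
    seg <- integer(n)
    seg[perm] <- rep_len(seq_len(nSegments), n)
    seg
  })
}

#' Segmented cross-validation of a PLS calibration
#'
#' Objects are randomly partitioned into near-equal segments (default 20);
#' each segment is held out in turn and the full pipeline - pre-treatment
#' fitting (e.g. the MSC reference), centering and NIPALS - is refit on the
#' remaining objects, so no information leaks from held-out beans into the
#' fold's model. Pooled held-out residuals give RMSECV per LV; the full-data
#' fit gives RMSEC per LV. Metrics (R2c, R2cv, RMSEC, RMSECV, RPD, error as
#' percent of range) are reported at the selected LV.
#'
#' @param X objects x bands matrix of raw spectra, or a
#'   \code{\link{SpectralDataset}}.
#' @param y response vector, or (for a dataset) use \code{analyte}.
#' @param maxLV largest LV to evaluate.
#' @param nSegments number of CV segments (default 20).
#' @param seed RNG seed for segment assignment (recorded in the result).
#' @param chain \code{\link{PreprocessChain}} applied inside each fold.
#' @param analyte analyte name when \code{X} is a dataset.
#' @param lvTol tolerance passed to \code{\link{selectLV}}.
#' @return list with \code{model} (the full-data \code{\link{PLSModel}} at
#'   the chosen LV) and \code{cv} (a \code{\link{CVResult}}).
#' @export
crossValidate <- function(X, y = NULL, maxLV, nSegments = 20L, seed = 1L,
                          chain = preprocessChain(), analyte = NA_character_,
                          lvTol = 0.02) {
  wl <- NULL; basis <- "as_is"
  if (is(X, "SpectralDataset")) {
    wl <- wavelengths(X)
    basis <- S4Vectors::metadata(X)$basis %||% "as_is"
    if (is.null(y)) y <- referenceValues(X, analyte)
    X <- spectraMatrix(X)
  }
  X <- .asSpectraMatrix(X)
  n <- nrow(X)
  nSegments <- as.integer(nSegments)
  if (n < nSegments)
    stop(sprintf("only %d objects for %d segments; use leave-one-out (nSegments = n)",
                 n, nSegments))
  maxLV <- min(as.integer(maxLV), ncol(X),
               n - ceiling(n / nSegments) - 1L)
  if (maxLV < 1L) stop("too few objects for cross-validation")

  seg <- .makeSegments(n, nSegments, seed)

  predCV <- matrix(NA_real_, n, maxLV)
  for (s in seq_len(nSegments)) {
    hold <- seg == s
    chainF <- fitChain(chain, X[!hold, , drop = FALSE])
    Xtr <- applyChain(chainF, X[!hold, , drop = FALSE])
    Xte <- applyChain(chainF, X[hold, , drop = FALSE])
    xm <- colMeans(Xtr); ym <- mean(y[!hold])
    fit <- .nipals(sweep(Xtr, 2, xm), y[!hold] - ym,
                   min(maxLV, nrow(Xtr) - 1L))
    Xc <- sweep(Xte, 2, xm)
    acc <- rep(ym, sum(hold))
    for (k in seq_len(maxLV)) {
      if (k <= fit$nlv) {
        t <- Xc %*% fit$W[, k]
        acc <- acc + as.vector(t) * fit$q[k]
        Xc <- Xc - t %*% t(fit$P[, k])
      }
      predCV[hold, k] <- acc
    }
  }

  # full-data calibration curve
  chainAll <- fitChain(chain, X)
  Xall <- applyChain(chainAll, X)
  xm <- colMeans(Xall); ym <- mean(y)
  fitAll <- .nipals(sweep(Xall, 2, xm), y - ym, maxLV)
  predC <- matrix(ym, n, maxLV)
  Xc <- sweep(Xall, 2, xm)
  acc <- rep(ym, n)
  for (k in seq_len(fitAll$nlv)) {
    t <- Xc %*% fitAll$W[, k]
    acc <- acc + as.vector(t) * fitAll$q[k]
    Xc <- Xc - t %*% t(fitAll$P[, k])
    predC[, k:maxLV] <- acc
  }

  rmsecCurve <- vapply(seq_len(maxLV), function(k) rmse(predC[, k], y), numeric(1))
  rmsecvCurve <- vapply(seq_len(maxLV), function(k) rmse(predCV[, k], y), numeric(1))
  lv <- selectLV(rmsecvCurve, tol = lvTol)

  cv <- new("CVResult",
            rmsecCurve = rmsecCurve, rmsecvCurve = rmsecvCurve,
            chosenLV = lv,
            r2c = r2(predC[, lv], y), r2cv = r2(predCV[, lv], y),
            rmsec = rmsecCurve[lv], rmsecv = rmsecvCurve[lv],
            rpd = rpd(sd(y), rmsecvCurve[lv]),
            errorPctRange = errorPctRange(rmsecvCurve[lv], min(y), max(y)),
            seed = as.integer(seed), segments = seg)
  model <- fitPLS(X, y, nlv = lv, analyte = analyte, chain = chain,
                  wavelengths = wl, basis = basis)
  list(model = model, cv = cv)
}

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d LV (of %d evaluated), %d-segment CV (seed %d)\n",
              object@chosenLV, length(object@rmsecvCurve),
              max(object@segments), object@seed))
  cat(sprintf("  R2c = %.3f  RMSEC = %.3f\n", object@r2c, object@rmsec))
  cat(sprintf("  R2cv = %.3f  RMSECV = %.3f\n", object@r2cv, object@rmsecv))
  cat(sprintf("  RPD = %.2f   error %% of range = %.1f\n",
              object@rpd, object@errorPctRange))
})
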