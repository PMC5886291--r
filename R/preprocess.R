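# Spectral pre-treatments. All operators act row-wise on an objects x bands
# matrix (a single spectrum is treated as a 1-row matrix) and are
# deterministic; only the MSC reference is data-driven, and it is stored on
# the chain after fitting so the chain replays identically on new spectra.

.asSpectraMatrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Standard Normal Variate transform
#'
#' Centres and scales each spectrum to zero mean and unit (n-1) standard
#' deviation, removing per-spectrum additive and multiplicative scatter.
#'
#' @param x spectrum (numeric vector) or objects x bands matrix.
#' @return transformed object of the same shape.
#' @examples
#' snv(c(1, 2, 3, 4, 5))  # mean 0, sd 1
#' @export
snv <- function(x) {
  vec <- is.null(dim(x))
  m <- .asSpectraMatrix(x)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s < 1e-14))
    stop("SNV undefined for constant spectrum (row ",
         paste(which(s < 1e-14), collapse = ", "), ")")
  out <- sweep(sweep(m, 1, mu), 1, s, "/")
  if (vec) out[1, ] else out
}

#' Fit a Multiplicative Scatter Correction reference
#'
#' The MSC reference is the column (band-wise) mean of the calibration
#' spectra.
#'
#' @param spectra objects x bands matrix, at least two rows.
#' @return numeric reference spectrum.
#' @export
mscFit <- function(spectra) {
  spectra <- .asSpectraMatrix(spectra)
  if (nrow(spectra) < 2L) stop("MSC fitting needs at least two spectra")
  colMeans(spectra)
}

#' Apply Multiplicative Scatter Correction
#'
#' Each spectrum x is regressed on the reference as x ~ a * ref + b by least
#' squares, and corrected to (x - b) / a.
#'
#' @param x spectrum or objects x bands matrix.
#' @param reference reference spectrum from \code{\link{mscFit}}.
#' @param tol minimum |a| (default 1e-8).
#' @return corrected object of the same shape.
#' @export
mscApply <- function(x, reference, tol = 1e-8) {
  vec <- is.null(dim(x))
  m <- .asSpectraMatrix(x)
  if (ncol(m) != length(reference)) stop("spectrum and MSC reference lengths differ")
  rc <- reference - mean(reference)
  vr <- sum(rc^2)
  a <- as.vector((m %*% rc)) / vr
  b <- rowMeans(m) - a * mean(reference)
  small <- abs(a) < tol
  if (any(small))
    stop("MSC slope below tolerance for spectrum (row ",
         paste(which(small), collapse = ", "), ")")
  out <- sweep(sweep(m, 1, b), 1, a, "/")
  if (vec) out[1, ] else out
}

# Savitzky-Golay weight matrix: out = X %*% t(W). Row i of W holds the
# derivative weights for output band i; interior rows use the centred window,
# the first/last h rows refit the polynomial on the truncated one-sided
# window so spectrum length is preserved for pixel-wise mapping.
.savgolWeights <- function(nBands, order, window, poly) {
  if (window %% 2L == 0L) stop("Savitzky-Golay window must be odd")
  if (window <= poly) stop("Savitzky-Golay window must exceed the polynomial order")
  if (nBands < window) stop("spectrum shorter than the smoothing window")
  h <- (window - 1L) %/% 2L
  W <- matrix(0, nBands, nBands)
  for (i in seq_len(nBands)) {
    j <- max(1L, i - h):min(nBands, i + h)
    t <- j - i
    V <- outer(t, 0:poly, `^`)
    # coefficient row for derivative `order` at t = 0: factorial(order) * c_order
    coefRows <- solve(crossprod(V), t(V))
    W[i, j] <- factorial(order) * coefRows[order + 1L, ]
  }
  W
}

#' Savitzky-Golay derivative
#'
#' Derivative of a local least-squares polynomial fit in a sliding window,
#' evaluated at each band with respect to band index (the 980-2500 nm grid is
#' treated as uniformly spaced, the usual chemometrics convention). Edges are
#' handled by refitting the polynomial on the truncated one-sided window, so
#' output length equals input length.
#'
#' @param x spectrum or objects x bands matrix.
#' @param order derivative order, 1 or 2.
#' @param window odd window length (default 5).
#' @param poly polynomial order (default 2), less than \code{window}.
#' @return derivative of the same shape as \code{x}.
#' @export
savgolDerivative <- function(x, order = 1L, window = 5L, poly = 2L) {
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2")
  vec <- is.null(dim(x))
  m <- .asSpectraMatrix(x)
  W <- .savgolWeights(ncol(m), as.integer(order), as.integer(window), as.integer(poly))
  out <- m %*% t(W)
  if (vec) out[1, ] else out
}

#' De-trend a spectrum
#'
#' Residual after a least-squares polynomial (in band index) is removed from
#' each spectrum.
#'
#' @param x spectrum or objects x bands matrix.
#' @param degree polynomial degree (default 2).
#' @return residual of the same shape as \code{x}.
#' @export
detrend <- function(x, degree = 2L) {
  vec <- is.null(dim(x))
  m <- .asSpectraMatrix(x)
  idx <- seq_len(ncol(m))
  B <- outer(idx, 0:degree, `^`)
  Q <- qr.Q(qr(B))
  out <- m - (m %*% Q) %*% t(Q)
  if (vec) out[1, ] else out
}

#' Build a pre-treatment chain
#'
#' @param ... steps in application order; each is a list with \code{name}
#'   (one of \code{snv}, \code{msc}, \code{savgol_derivative},
#'   \code{detrend}, \code{none}) and its parameters. Convenience strings are
#'   accepted: \code{"snv"}, \code{"msc"}, \code{"sg1"}/\code{"sg2"} (5-point
#'   window, 2nd-order polynomial, 1st/2nd derivative), \code{"detrend"},
#'   \code{"none"}.
#' @return a \code{\link{PreprocessChain}}.
#' @examples
#' preprocessChain("snv", "sg1")   # the SNV + 1st-derivative treatment
#' @export
preprocessChain <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) {
      s <- switch(s,
        snv = list(name = "snv"),
        msc = list(name = "msc"),
        sg1 = list(name = "savgol_derivative", order = 1L, window = 5L, poly = 2L),
        sg2 = list(name = "savgol_derivative", order = 2L, window = 5L, poly = 2L),
        detrend = list(name = "detrend", degree = 2L),
        none = list(name = "none"),
        stop("unknown pre-treatment shorthand: ", s))
    }
    s
  })
  new("PreprocessChain", steps = steps)
}

#' Fit the data-driven parts of a chain
#'
#' Runs the chain over calibration spectra, fitting any MSC step's reference
#' on the spectra as they arrive at that step, and stores the reference on
#' the chain. Chains without MSC are returned unchanged.
#'
#' @param chain a \code{\link{PreprocessChain}}.
#' @param spectra objects x bands calibration matrix.
#' @return the chain with fitted references stored.
#' @export
fitChain <- function(chain, spectra) {
  m <- .asSpectraMatrix(spectra)
  steps <- chain@steps
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (identical(s$name, "msc") && is.null(s$reference)) {
      steps[[i]]$reference <- mscFit(m)
      s <- steps[[i]]
    }
    m <- .applyStep(s, m)
  }
  new("PreprocessChain", steps = steps)
}

.applyStep <- function(s, m) {
  switch(s$name,
    none = m,
    snv = snv(m),
    msc = {
      if (is.null(s$reference))
        stop("MSC step has no fitted reference; call fitChain() first")
      mscApply(m, s$reference)
    },
    savgol_derivative = savgolDerivative(m, order = s$order %||% 1L,
                                         window = s$window %||% 5L,
                                         poly = s$poly %||% 2L),
    detrend = detrend(m, degree = s$degree %||% 2L),
    stop("unknown step: ", s$name))
}

#' Apply a pre-treatment chain
#'
#' Steps are applied in listed order. Every operator is row-local (MSC uses
#' its stored reference), so batch application and row-by-row application
#' give identical results.
#'
#' @param chain a \code{\link{PreprocessChain}} (MSC steps must be fitted).
#' @param x spectrum or objects x bands matrix.
#' @return transformed object of the same shape.
#' @export
applyChain <- function(chain, x) {
  vec <- is.null(dim(x))
  m <- .asSpectraMatrix(x)
  for (s in chain@steps) m <- .applyStep(s, m)
  if (vec) m[1, ] else m
}

#' Serialise / deserialise a chain as JSON
#'
#' @param chain a \code{\link{PreprocessChain}}.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return \code{chainToJSON}: JSON string (invisibly when written to file);
#'   \code{chainFromJSON}: a \code{\link{PreprocessChain}}.
#' @export
chainToJSON <- function(chain, path = NULL) {
  # 17 significant digits: lossless decimal round trip for IEEE doubles
  js <- jsonlite::toJSON(list(steps = chain@steps), digits = I(17), auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname chainToJSON
#' @param json JSON string or file path produced by \code{chainToJSON}.
#' @export
chainFromJSON <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- paste(readLines(json), collapse = "")
  parsed <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  steps <- lapply(parsed$steps, function(s) {
    s$name <- as.character(s$name)
    for (k in c("order", "window", "poly", "degree"))
      if (!is.null(s[[k]])) s[[k]] <- as.integer(s[[k]])
    if (!is.null(s$reference)) s$reference <- as.numeric(unlist(s$reference))
    s
  })
  new("PreprocessChain", steps = steps)
}

setMethod("show", "PreprocessChain", function(object) {
  if (length(object@steps) == 0L) { cat("PreprocessChain: (identity)\n"); return(invisible()) }
  lab <- vapply(object@steps, function(s) {
    if (s$name == "savgol_derivative")
      sprintf("savgol(d%d, w%d, p%d)", s$order %||% 1L, s$window %||% 5L, s$poly %||% 2L)
    else if (s$name == "msc" && !is.null(s$reference)) "msc(fitted)"
    else s$name
  }, character(1))
  cat("PreprocessChain:", paste(lab, collapse = " -> "), "\n")
})
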