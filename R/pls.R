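#' Assemble a spectral dataset
#'
#' Pairs object mean spectra with reference concentrations and metadata in a
#' \code{\link{SpectralDataset}} (a \code{SummarizedExperiment} whose assay
#' is bands x objects).
#'
#' @param spectra objects x bands matrix of mean absorbance spectra.
#' @param wavelengths numeric wavelength grid, nm.
#' @param concentrations data.frame of reference values (mg/g), one row per
#'   object; typically columns sucrose, caffeine, trigonelline.
#' @param species optional character vector (\code{"arabica"}/
#'   \code{"robusta"}).
#' @param beanId optional object identifiers.
#' @param batch optional batch labels.
#' @param basis \code{"as_is"} (default) or \code{"dwb"}.
#' @return a \code{\link{SpectralDataset}}.
#' @export
spectralDataset <- function(spectra, wavelengths, concentrations,
                            species = NULL, beanId = NULL, batch = NULL,
                            basis = "as_is") {
  spectra <- .asSpectraMatrix(spectra)
  n <- nrow(spectra)
  stopifnot(ncol(spectra) == length(wavelengths), nrow(concentrations) == n)
  if (anyNA(spectra)) stop("spectra must contain no missing values after assembly")
  cd <- S4Vectors::DataFrame(
    beanId = beanId %||% seq_len(n),
    species = species %||% rep(NA_character_, n),
    batch = batch %||% rep(NA_character_, n),
    as.data.frame(concentrations))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = t(spectra)),
    rowData = S4Vectors::DataFrame(wavelength = wavelengths),
    colData = cd)
  S4Vectors::metadata(se)$basis <- basis
  new("SpectralDataset", se)
}

#' @describeIn wavelengths wavelength grid of a spectral dataset
#' @export
setMethod("wavelengths", "SpectralDataset", function(x)
  SummarizedExperiment::rowData(x)$wavelength)

#' Objects x bands spectra matrix of a dataset
#'
#' @param x a \code{\link{SpectralDataset}}.
#' @return numeric matrix, objects in rows.
#' @export
spectraMatrix <- function(x) t(SummarizedExperiment::assay(x, "absorbance"))

#' Reference values for one analyte
#'
#' @param x a \code{\link{SpectralDataset}}.
#' @param analyte column name in the dataset's colData (e.g.
#'   \code{"caffeine"}).
#' @return numeric vector, mg/g.
#' @export
referenceValues <- function(x, analyte) {
  cd <- SummarizedExperiment::colData(x)
  if (!analyte %in% colnames(cd)) stop("no reference column '", analyte, "' in dataset")
  as.numeric(cd[[analyte]])
}

# --- PLS1 (NIPALS) ---------------------------------------------------------

# Core NIPALS PLS1 on already-centred matrices. For a single response the
# NIPALS inner loop contracts in one pass, but the iteration is retained with
# a convergence guard (relative score change < tol, max 500 iterations).
.nipals <- function(Xc, yc, nlv, tol = 1e-10, maxIter = 500L) {
  nb <- ncol(Xc)
  W <- matrix(0, nb, nlv); P <- matrix(0, nb, nlv)
  q <- numeric(nlv); Tm <- matrix(0, nrow(Xc), nlv)
  for (k in seq_len(nlv)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { nlv <- k - 1L; break }
    w <- w / nw
    t <- Xc %*% w
    iter <- 0L
    repeat {
      iter <- iter + 1L
      qk <- sum(yc * t) / sum(t^2)
      u <- yc / qk
      wNew <- crossprod(Xc, u)
      wNew <- wNew / sqrt(sum(wNew^2))
      tNew <- Xc %*% wNew
      delta <- sqrt(sum((tNew - t)^2)) / max(sqrt(sum(tNew^2)), 1e-300)
      w <- wNew; t <- tNew
      if (delta < tol) break
      if (iter >= maxIter)
        stop("NIPALS failed to converge after ", maxIter, " iterations")
    }
    tt <- sum(t^2)
    p <- crossprod(Xc, t) / tt
    qk <- sum(yc * t) / tt
    W[, k] <- w; P[, k] <- p; q[k] <- qk; Tm[, k] <- t
    Xc <- Xc - t %*% t(p)
    yc <- yc - t * qk
  }
  if (nlv == 0L) stop("response has no covariance with the spectra")
  list(W = W[, seq_len(nlv), drop = FALSE], P = P[, seq_len(nlv), drop = FALSE],
       q = q[seq_len(nlv)], scores = Tm[, seq_len(nlv), drop = FALSE], nlv = nlv)
}

.plsBeta <- function(W, P, q) {
  # beta = W (P'W)^-1 q
  as.vector(W %*% solve(crossprod(P, W), q))
}

#' Fit a PLS1 regression model
#'
#' NIPALS partial least squares with a single response on column-centred
#' spectra and centred response (no autoscaling, the common chemometrics
#' default). The collapsed regression-coefficient vector (beta) is computed
#' from the weights and loadings; predictions via the latent-score route and
#' via beta agree to numerical precision.
#'
#' @param X objects x bands matrix of pre-treated spectra, or a
#'   \code{\link{SpectralDataset}}.
#' @param y response vector (mg/g); or, for a dataset, the analyte name via
#'   \code{analyte}.
#' @param nlv number of latent variables; 0 gives the mean model.
#' @param analyte analyte name when \code{X} is a dataset.
#' @param chain optional \code{\link{PreprocessChain}}; when supplied it is
#'   fitted on \code{X} and applied before the regression, and stored on the
#'   model so pixel-level prediction replays it.
#' @param wavelengths wavelength grid (taken from a dataset automatically).
#' @param basis basis tag for bookkeeping.
#' @return a \code{\link{PLSModel}}.
#' @export
fitPLS <- function(X, y = NULL, nlv, analyte = NA_character_,
                   chain = preprocessChain(), wavelengths = NULL,
                   basis = "as_is") {
  if (is(X, "SpectralDataset")) {
    wavelengths <- wavelengths %||% wavelengths(X)
    if (is.null(y)) y <- referenceValues(X, analyte)
    X <- spectraMatrix(X)
  }
  X <- .asSpectraMatrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least two objects")
  if (sd(y) < 1e-14) stop("response has zero variance")
  nlv <- as.integer(nlv)
  if (nlv > min(n - 1L, ncol(X)))
    stop("nlv must not exceed min(n - 1, bands) = ", min(n - 1L, ncol(X)))

  chain <- fitChain(chain, X)
  Xp <- applyChain(chain, X)
  xm <- colMeans(Xp)
  ym <- mean(y)
  if (nlv == 0L) {
    return(new("PLSModel", nlv = 0L,
               weights = matrix(0, ncol(Xp), 0), xloadings = matrix(0, ncol(Xp), 0),
               yloadings = numeric(0), xcenter = xm, ycenter = ym,
               beta = rep(0, ncol(Xp)), intercept = ym,
               wavelengths = wavelengths %||% seq_len(ncol(Xp)),
               chain = chain, analyte = analyte, basis = basis))
  }
  fit <- .nipals(sweep(Xp, 2, xm), y - ym, nlv)
  beta <- .plsBeta(fit$W, fit$P, fit$q)
  new("PLSModel", nlv = fit$nlv, weights = fit$W, xloadings = fit$P,
      yloadings = fit$q, xcenter = xm, ycenter = ym, beta = beta,
      intercept = ym - sum(xm * beta),
      wavelengths = wavelengths %||% seq_len(ncol(Xp)),
      chain = chain, analyte = analyte, basis = basis)
}

#' @describeIn fitPLS collapsed regression coefficients (beta) of the model.
#' @param object a \code{PLSModel}.
#' @param ... unused.
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@beta)

#' Predict from a PLS model
#'
#' Applies the model's stored pre-treatment chain, then the collapsed
#' regression coefficients. \code{route = "scores"} instead projects through
#' the latent variables; both routes agree to numerical precision.
#'
#' @param object a \code{\link{PLSModel}}.
#' @param newdata spectrum, objects x bands matrix, or
#'   \code{\link{SpectralDataset}} of raw (un-pre-treated) spectra.
#' @param route \code{"beta"} (default) or \code{"scores"}.
#' @param applyChainFirst set FALSE when \code{newdata} is already
#'   pre-treated.
#' @param ... unused.
#' @return numeric predictions, mg/g.
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          route = c("beta", "scores"),
                                          applyChainFirst = TRUE, ...) {
  route <- match.arg(route)
  if (is(newdata, "SpectralDataset")) newdata <- spectraMatrix(newdata)
  m <- .asSpectraMatrix(newdata)
  if (ncol(m) != length(object@xcenter))
    stop(sprintf("model expects %d bands, got %d", length(object@xcenter), ncol(m)))
  if (applyChainFirst) m <- applyChain(object@chain, m)
  if (route == "beta" || object@nlv == 0L)
    return(as.vector(m %*% object@beta) + object@intercept)
  Xc <- sweep(m, 2, object@xcenter)
  pred <- rep(object@ycenter, nrow(m))
  for (k in seq_len(object@nlv)) {
    t <- Xc %*% object@weights[, k]
    pred <- pred + as.vector(t) * object@yloadings[k]
    Xc <- Xc - t %*% t(object@xloadings[, k])
  }
  pred
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %s (%s), %d LV, %d bands\n",
              ifelse(is.na(object@analyte), "<unnamed>", object@analyte),
              object@basis, object@nlv, length(object@beta)))
  show(object@chain)
})

#' Save / load a PLS model as JSON
#'
#' Stores the pre-treatment chain (including any fitted MSC reference),
#' centering vectors, weights/loadings, beta coefficients and metadata.
#'
#' @param model a \code{\link{PLSModel}}.
#' @param path JSON file path.
#' @return \code{writePLSModel}: invisibly, the path. \code{readPLSModel}:
#'   the model.
#' @export
writePLSModel <- function(model, path) {
  obj <- list(nlv = model@nlv, weights = model@weights,
              xloadings = model@xloadings, yloadings = model@yloadings,
              xcenter = model@xcenter, ycenter = model@ycenter,
              beta = model@beta, intercept = model@intercept,
              wavelengths = model@wavelengths,
              chain = model@chain@steps, analyte = model@analyte,
              basis = model@basis)
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname writePLSModel
#' @export
readPLSModel <- function(path) {
  o <- jsonlite::fromJSON(paste(readLines(path), collapse = ""),
                          simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  steps <- lapply(o$chain, function(s) {
    for (k in c("order", "window", "poly", "degree"))
      if (!is.null(s[[k]])) s[[k]] <- as.integer(s[[k]])
    if (!is.null(s$reference)) s$reference <- as.numeric(unlist(s$reference))
    s
  })
  nb <- length(o$beta)
  new("PLSModel", nlv = as.integer(o$nlv),
      weights = matrix(unlist(o$weights), nrow = nb),
      xloadings = matrix(unlist(o$xloadings), nrow = nb),
      yloadings = as.numeric(unlist(o$yloadings)),
      xcenter = as.numeric(o$xcenter), ycenter = as.numeric(o$ycenter),
      beta = as.numeric(o$beta), intercept = as.numeric(o$intercept),
      wavelengths = as.numeric(o$wavelengths),
      chain = new("PreprocessChain", steps = steps),
      analyte = as.character(o$analyte), basis = as.character(o$basis))
}

# --- metrics ---------------------------------------------------------------

#' Root mean square error
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @return \eqn{\sqrt{\mathrm{mean}((pred-obs)^2)}}.
#' @export
rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

#' Coefficient of determination
#'
#' @param pred predicted values.
#' @param obs observed values.
#' @return \eqn{1 - SS_{res}/SS_{tot}}.
#' @export
r2 <- function(pred, obs) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Ratio of performance deviation
#'
#' RPD is the ratio between the standard deviation of the reference values
#' and the cross-validation error; higher is better (values around 2 are
#' usable for quantification, around 1.4 only for rough screening).
#'
#' @param sdRef standard deviation of the reference measurements.
#' @param rmsecv cross-validation RMSE.
#' @return dimensionless ratio.
#' @examples
#' rpd(2.0, 1.022)   # ~ 2.0 (trigonelline-like)
#' rpd(10.2, 7.250)  # ~ 1.4 (sucrose-like)
#' @export
rpd <- function(sdRef, rmsecv) sdRef / rmsecv

#' Cross-validation error as a percentage of the reference range
#'
#' @param rmsecv cross-validation RMSE.
#' @param yMin,yMax observed minimum and maximum of the reference values.
#' @return \eqn{100 \cdot rmsecv / (yMax - yMin)}, percent.
#' @examples
#' errorPctRange(7.250, 5.3, 70.8)  # ~ 11.1
#' @export
errorPctRange <- function(rmsecv, yMin, yMax) {
  if (yMax <= yMin) stop("yMax must exceed yMin")
  100 * rmsecv / (yMax - yMin)
}
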