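#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Raw line-scan hypercube with calibration references
#'
#' Holds the detector counts of one push-broom scan together with the white
#' and dark reference frames and the exposure times needed to convert counts
#' to reflectance. The white and dark references are per-(sample, band)
#' detector frames; a white cube acquired over several scan lines is averaged
#' down to one frame on ingestion to suppress line noise.
#'
#' @slot intensity numeric array, lines x samples x bands, detector counts.
#' @slot white numeric matrix, samples x bands.
#' @slot darkSample numeric matrix, samples x bands (shutter closed, sample
#'   exposure).
#' @slot darkWhite numeric matrix, samples x bands (shutter closed, white
#'   exposure).
#' @slot exposureSample sample integration time, milliseconds.
#' @slot exposureWhite white-reference integration time, milliseconds.
#' @slot wavelengths numeric vector, nm, strictly increasing, length = bands.
#' @slot metadata list of provenance fields (source paths, instrument notes).
#' @export
setClass("RawScan", representation(
  intensity = "array",
  white = "matrix",
  darkSample = "matrix",
  darkWhite = "matrix",
  exposureSample = "numeric",
  exposureWhite = "numeric",
  wavelengths = "numeric",
  metadata = "list"
))

setValidity("RawScan", function(object) {
  d <- dim(object@intensity)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "intensity must be a 3-D array (lines x samples x bands)")
  else {
    if (!all(dim(object@white) == d[2:3])) msg <- c(msg, "white must be samples x bands")
    if (!all(dim(object@darkSample) == d[2:3])) msg <- c(msg, "darkSample must be samples x bands")
    if (!all(dim(object@darkWhite) == d[2:3])) msg <- c(msg, "darkWhite must be samples x bands")
    if (length(object@wavelengths) != d[3]) msg <- c(msg, "wavelength length must equal band count")
  }
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (object@exposureSample <= 0 || object@exposureWhite <= 0)
    msg <- c(msg, "exposure times must be positive")
  if (length(msg)) msg else TRUE
})

#' Calibrated hypercube
#'
#' A 3-D spectral image in reflectance or absorbance units. Invalid elements
#' (non-positive calibration denominators, non-positive reflectance under the
#' log transform) are carried as \code{NA} and propagate as missing through
#' all downstream means.
#'
#' @slot values numeric array, lines x samples x bands; NA marks masked
#'   elements.
#' @slot wavelengths numeric vector, nm, length = bands.
#' @slot unit \code{"counts"} (uncalibrated), \code{"reflectance"} or
#'   \code{"absorbance"}.
#' @slot metadata list: source files, exposure times, trim applied, counts of
#'   masked / flagged-high elements.
#' @export
setClass("Hypercube", representation(
  values = "array",
  wavelengths = "numeric",
  unit = "character",
  metadata = "list"
))

setValidity("Hypercube", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-D array (lines x samples x bands)")
  else if (length(object@wavelengths) != d[3])
    msg <- c(msg, "wavelength length must equal band count")
  if (!object@unit %in% c("counts", "reflectance", "absorbance"))
    msg <- c(msg, "unit must be 'counts', 'reflectance' or 'absorbance'")
  if (length(msg)) msg else TRUE
})

#' Bad detector element map
#'
#' Defective (sample, band) detector coordinates of a push-broom camera; a bad
#' element corrupts every scan line at that position.
#'
#' @slot coords integer matrix with columns \code{sample}, \code{band}
#'   (1-based).
#' @slot detectorDim integer vector c(samples, bands).
#' @export
setClass("BadPixelMap", representation(
  coords = "matrix",
  detectorDim = "integer"
))

setValidity("BadPixelMap", function(object) {
  if (nrow(object@coords) == 0L) return(TRUE)
  ok <- object@coords[, 1L] >= 1L & object@coords[, 1L] <= object@detectorDim[1L] &
    object@coords[, 2L] >= 1L & object@coords[, 2L] <= object@detectorDim[2L]
  if (all(ok)) TRUE else "bad-pixel coordinates outside detector bounds"
})

#' One segmented bean
#'
#' @slot label integer region label.
#' @slot mask logical matrix (lines x samples), TRUE on bean pixels.
#' @slot pixelCount integer number of TRUE pixels.
#' @slot centroid numeric c(line, sample), 1-based pixel centre of mass.
#' @slot meanSpectrum numeric per-band mean absorbance over unmasked pixels.
#' @slot side \code{"up"}, \code{"down"} or \code{NA}.
#' @slot creaseMask logical matrix of pixels excluded as crease (same shape as
#'   \code{mask}); all-FALSE when no exclusion was applied.
#' @export
setClass("BeanRegion", representation(
  label = "integer",
  mask = "matrix",
  pixelCount = "integer",
  centroid = "numeric",
  meanSpectrum = "numeric",
  side = "character",
  creaseMask = "matrix"
))

setValidity("BeanRegion", function(object) {
  msg <- character()
  if (object@pixelCount != sum(object@mask)) msg <- c(msg, "pixelCount must equal sum(mask)")
  if (!all(dim(object@creaseMask) == dim(object@mask)))
    msg <- c(msg, "creaseMask shape must match mask")
  if (length(msg)) msg else TRUE
})

#' Segmentation of one hypercube into beans
#'
#' @slot labelImage integer matrix (lines x samples); 0 = background.
#' @slot regions list of \code{BeanRegion}, ordered row-major by centroid.
#' @slot parameters list of the parameters used.
#' @export
setClass("SegmentationResult", representation(
  labelImage = "matrix",
  regions = "list",
  parameters = "list"
))

setValidity("SegmentationResult", function(object) {
  lab <- sort(unique(as.integer(object@labelImage[object@labelImage != 0L])))
  got <- sort(vapply(object@regions, function(r) r@label, integer(1)))
  if (!identical(lab, got)) "regions must match the distinct nonzero labels" else TRUE
})

#' Spectral pre-treatment chain
#'
#' An ordered, replayable list of pre-treatment steps. Step names are one of
#' \code{snv}, \code{msc}, \code{savgol_derivative}, \code{detrend},
#' \code{none}. The MSC step stores its fitted reference spectrum so the
#' chain can be replayed identically on new spectra (including single pixel
#' spectra at prediction time).
#'
#' @slot steps list; each element is a list with \code{name} and parameters.
#' @export
setClass("PreprocessChain", representation(steps = "list"))

setValidity("PreprocessChain", function(object) {
  ok <- c("snv", "msc", "savgol_derivative", "detrend", "none")
  for (s in object@steps) {
    if (is.null(s$name) || !s$name %in% ok)
      return(sprintf("unknown step name; must be one of %s", paste(ok, collapse = ", ")))
    if (identical(s$name, "savgol_derivative")) {
      w <- s$window %||% 5L; p <- s$poly %||% 2L
      if (w %% 2L == 0L) return("savgol window must be odd")
      if (w <= p) return("savgol window must exceed polynomial order")
    }
  }
  TRUE
})

#' Object-by-band spectral dataset
#'
#' Mean bean spectra paired with reference concentrations, stored as a
#' \code{SummarizedExperiment}: the assay is bands x objects, \code{rowData}
#' carries the wavelength grid, \code{colData} the per-bean metadata (bean
#' id, species, batch, basis) and the reference concentrations in mg/g.
#'
#' @export
setClass("SpectralDataset", contains = "SummarizedExperiment")

#' Fitted PLS1 latent-variable model
#'
#' NIPALS PLS1 on column-centred spectra and centred response. Predictions by
#' the latent-score route and by the collapsed regression-coefficient (beta)
#' route agree to numerical precision; both are stored.
#'
#' @slot nlv number of latent variables.
#' @slot weights X-weights, bands x nlv.
#' @slot xloadings X-loadings, bands x nlv.
#' @slot yloadings numeric, length nlv.
#' @slot xcenter column means of X.
#' @slot ycenter mean of y.
#' @slot beta collapsed regression coefficients, length = bands.
#' @slot intercept scalar intercept on the original scale.
#' @slot wavelengths wavelength grid the model expects (after any trim and
#'   band selection).
#' @slot chain attached \code{PreprocessChain} applied before the model.
#' @slot analyte response name (e.g. \code{"caffeine"}).
#' @slot basis \code{"as_is"} or \code{"dwb"}.
#' @export
setClass("PLSModel", representation(
  nlv = "integer",
  weights = "matrix",
  xloadings = "matrix",
  yloadings = "numeric",
  xcenter = "numeric",
  ycenter = "numeric",
  beta = "numeric",
  intercept = "numeric",
  wavelengths = "numeric",
  chain = "PreprocessChain",
  analyte = "character",
  basis = "character"
))

setValidity("PLSModel", function(object) {
  msg <- character()
  if (object@nlv > 0L) {
    if (ncol(object@weights) != object@nlv) msg <- c(msg, "weights must have nlv columns")
    if (length(object@yloadings) != object@nlv) msg <- c(msg, "yloadings length must equal nlv")
  }
  if (length(object@beta) != length(object@xcenter))
    msg <- c(msg, "beta length must equal number of bands")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' @slot rmsecCurve per-LV calibration RMSE.
#' @slot rmsecvCurve per-LV cross-validation RMSE (pooled held-out residuals).
#' @slot chosenLV latent variables selected (smallest LV within tolerance of
#'   the RMSECV minimum).
#' @slot r2c calibration R-squared at chosen LV.
#' @slot r2cv cross-validation R-squared at chosen LV.
#' @slot rmsec,rmsecv errors at chosen LV, response units (mg/g).
#' @slot rpd ratio of performance deviation: sd(reference) / RMSECV.
#' @slot errorPctRange RMSECV as percent of the observed reference range.
#' @slot seed RNG seed used for segment assignment.
#' @slot segments integer fold assignment per object.
#' @export
setClass("CVResult", representation(
  rmsecCurve = "numeric",
  rmsecvCurve = "numeric",
  chosenLV = "integer",
  r2c = "numeric",
  r2cv = "numeric",
  rmsec = "numeric",
  rmsecv = "numeric",
  rpd = "numeric",
  errorPctRange = "numeric",
  seed = "integer",
  segments = "integer"
))

#' Per-pixel chemical concentration image
#'
#' @slot map numeric matrix (lines x samples) of predicted concentration,
#'   mg/g; NA on background.
#' @slot analyte analyte name.
#' @slot basis \code{"as_is"} or \code{"dwb"}.
#' @slot labelImage integer matrix of bean labels matching \code{map}.
#' @slot perBean data.frame: label, nPixels, pixelMean, pixelSD, meanSpecPred
#'   (prediction on the bean's mean spectrum).
#' @slot bounds numeric c(lo, hi) default colour-scale bounds (1st-99th
#'   percentile of bean pixels).
#' @slot creaseFlag logical matrix marking crease pixels (predicted but
#'   flagged).
#' @export
setClass("ChemicalImage", representation(
  map = "matrix",
  analyte = "character",
  basis = "character",
  labelImage = "matrix",
  perBean = "data.frame",
  bounds = "numeric",
  creaseFlag = "matrix"
))

#' Pure-component absorbance library
#'
#' Synthetic Gaussian-peak absorbance profiles for sucrose, caffeine,
#' trigonelline and a bulk seed matrix on the instrument wavelength grid.
#' Peak positions follow the compounds' SWIR absorption features (caffeine
#' 1668/2250/2425 nm; trigonelline 1668/2269 nm; sucrose 1460-1700 nm region
#' and 2070 nm; matrix water/lipid bands 1430/1730/1760/1930/2250 nm).
#'
#' @slot wavelengths numeric, nm.
#' @slot spectra numeric matrix, bands x components, non-negative; columns
#'   sucrose, caffeine, trigonelline, matrix. Analyte columns are unit
#'   absorbance per mg/g.
#' @export
setClass("ComponentLibrary", representation(
  wavelengths = "numeric",
  spectra = "matrix"
))

setValidity("ComponentLibrary", function(object) {
  msg <- character()
  if (nrow(object@spectra) != length(object@wavelengths))
    msg <- c(msg, "spectra rows must match wavelengths")
  if (any(object@spectra < 0)) msg <- c(msg, "component spectra must be non-negative")
  if (!all(c("sucrose", "caffeine", "trigonelline", "matrix") %in% colnames(object@spectra)))
    msg <- c(msg, "spectra must have columns sucrose, caffeine, trigonelline, matrix")
  if (length(msg)) msg else TRUE
})

#' Synthetic study configuration
#'
#' Defaults emulate the single-bean study conditions: 10 beans per cube on a
#' dark stage, 256 bands over 980-2500 nm with the first 16 unusable,
#' per-species concentration means/SDs (Arabica sucrose 46.7 +/- 7.5,
#' caffeine 15.7 +/- 2.3, trigonelline 8.6 +/- 1.8 mg/g; Robusta 33.6 +/-
#' 9.1, 19.9 +/- 4.9, 7.3 +/- 1.7), inter-analyte correlations (sucrose to
#' caffeine -0.445, sucrose to trigonelline 0.395, caffeine to trigonelline
#' -0.185), truncation to the observed pooled ranges, bean-level
#' multiplicative scatter and band-wise detector noise.
#'
#' @slot params named list of generator parameters; see
#'   \code{\link{simulationConfig}} for the full set and defaults.
#' @export
setClass("SimulationConfig", representation(params = "list"))

setValidity("SimulationConfig", function(object) {
  p <- object@params
  msg <- character()
  if (any(unlist(p[c("scatterSlopeSD", "scatterOffsetSD", "noiseSD")]) < 0))
    msg <- c(msg, "noise and scatter SDs must be non-negative")
  if (any(p$concSDs < 0)) msg <- c(msg, "concentration SDs must be non-negative")
  ev <- eigen(p$corrMatrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) msg <- c(msg, "correlation matrix must be positive semi-definite")
  if (length(msg)) msg else TRUE
})
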