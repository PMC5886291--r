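#' @import methods
#' @importFrom stats coef predict median sd var lm lm.fit rnorm runif quantile setNames mad
#' @importFrom utils read.csv write.csv read.table write.table head
NULL

#' Wavelength vector of a spectral object
#'
#' @param x an object carrying a wavelength axis.
#' @return numeric vector of wavelengths in nanometres.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Data cube of a hyperspectral object
#'
#' @param x a \code{Hypercube} or \code{RawScan}.
#' @return numeric 3-D array, lines x samples x bands.
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' Unit tag of a hypercube
#'
#' @param x a \code{Hypercube}.
#' @return \code{"reflectance"} or \code{"absorbance"}.
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))

#' Segmented bean regions
#'
#' @param x a \code{SegmentationResult}.
#' @return list of \code{BeanRegion}.
#' @export
setGeneric("beanRegions", function(x) standardGeneric("beanRegions"))

#' Label image of a segmentation
#'
#' @param x a \code{SegmentationResult} or \code{ChemicalImage}.
#' @return integer matrix (lines x samples); 0 is background.
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' Convert reflectance to absorbance
#'
#' @param cube a reflectance \code{Hypercube}.
#' @param logBase logarithm base; NIRS convention is 10.
#' @return an absorbance \code{Hypercube}.
#' @export
setGeneric("toAbsorbance", function(cube, logBase = 10) standardGeneric("toAbsorbance"))

#' Drop leading spectral bands
#'
#' @param cube a \code{Hypercube} or \code{RawScan}.
#' @param nLeading number of leading bands to drop (sensor roll-off).
#' @return object of the same class with fewer bands.
#' @export
setGeneric("trimBands", function(cube, nLeading = 16L) standardGeneric("trimBands"))
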