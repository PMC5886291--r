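#' Calibrate raw counts to reflectance
#'
#' Converts detector counts to reflectance with white/dark references and
#' exposure-time correction:
#' \deqn{R = \frac{I - D_s}{W - D_w} \cdot \frac{t_w}{t_s}}
#' applied per pixel and band, where \eqn{I} is the recorded intensity,
#' \eqn{W} the white-reference signal, \eqn{D_s}/\eqn{D_w} the dark (shutter
#' closed) references for the sample and white exposures, and \eqn{t_s},
#' \eqn{t_w} the respective integration times. The exposure ratio accounts
#' for the white reference being acquired at a different exposure chosen for
#' its own dynamic range.
#'
#' Detector elements with a non-positive denominator \eqn{W - D_w} are masked
#' (NA) rather than clipped, with a warning reporting the count. Reflectance
#' above \code{cap} is physically suspect (specular glints) but unbounded by
#' the calibration equation, so such values are retained and only counted in
#' the metadata.
#'
#' @param scan a \code{\link{RawScan}}.
#' @param cap flag threshold for suspiciously high reflectance (default 2).
#' @return a reflectance \code{\link{Hypercube}}; metadata records the number
#'   of masked and flagged-high elements and the exposure times.
#' @examples
#' sc <- rawScan(array(60, c(2, 2, 3)), matrix(110, 2, 3),
#'               matrix(10, 2, 3), matrix(10, 2, 3),
#'               exposureSample = 1, exposureWhite = 2,
#'               wavelengths = c(1000, 1100, 1200))
#' range(cubeValues(calibrateReflectance(sc)))  # 1.0: (50/100) * 2
#' @export
calibrateReflectance <- function(scan, cap = 2.0) {
  stopifnot(is(scan, "RawScan"))
  validObject(scan)
  d <- dim(scan@intensity)
  denom <- scan@white - scan@darkWhite
  bad <- denom <= 0
  denom[bad] <- NA_real_
  ratio <- scan@exposureWhite / scan@exposureSample
  # broadcast the (samples x bands) frames across lines
  R <- array(NA_real_, dim = d)
  for (b in seq_len(d[3])) {
    num <- scan@intensity[, , b] - matrix(scan@darkSample[, b], d[1], d[2], byrow = TRUE)
    R[, , b] <- num / matrix(denom[, b], d[1], d[2], byrow = TRUE) * ratio
  }
  nBad <- sum(bad)
  if (nBad > 0)
    warning(sprintf("%d detector element(s) had non-positive white-dark denominator; masked", nBad))
  nHigh <- sum(R > cap, na.rm = TRUE)
  new("Hypercube", values = R, wavelengths = scan@wavelengths, unit = "reflectance",
      metadata = c(scan@metadata,
                   list(exposureSample = scan@exposureSample,
                        exposureWhite = scan@exposureWhite,
                        maskedElements = nBad * d[1], flaggedHigh = nHigh,
                        reflectanceCap = cap)))
}

#' @describeIn toAbsorbance absorbance \eqn{A = \log_{10}(1/R)}; elements with
#'   \eqn{R \le 0} are masked.
#' @export
setMethod("toAbsorbance", "Hypercube", function(cube, logBase = 10) {
  if (cube@unit != "reflectance")
    stop("toAbsorbance expects a reflectance cube, got unit '", cube@unit, "'")
  v <- cube@values
  v[v <= 0] <- NA_real_
  A <- -log(v, base = logBase)
  new("Hypercube", values = A, wavelengths = cube@wavelengths, unit = "absorbance",
      metadata = c(cube@metadata, list(logBase = logBase)))
})

#' Build a bad detector element map
#'
#' @param coords integer matrix (n x 2) of 1-based (sample, band) detector
#'   coordinates, or NULL for an empty map.
#' @param detectorDim integer c(samples, bands).
#' @return a \code{\link{BadPixelMap}}.
#' @export
badPixelMap <- function(coords = NULL, detectorDim) {
  if (is.null(coords)) coords <- matrix(integer(), ncol = 2L)
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("sample", "band")))
  new("BadPixelMap", coords = coords, detectorDim = as.integer(detectorDim))
}

#' Auto-detect dead detector columns
#'
#' A dead (sample, band) element of a push-broom detector produces the same
#' count on every scan line; elements whose variance across lines falls below
#' \code{tol} are flagged.
#'
#' @param scan a \code{\link{RawScan}}.
#' @param tol variance threshold (counts squared).
#' @return a \code{\link{BadPixelMap}}.
#' @export
detectBadPixels <- function(scan, tol = 1e-12) {
  v <- apply(scan@intensity, c(2, 3), var)
  idx <- which(v <= tol, arr.ind = TRUE)
  badPixelMap(idx, dim(scan@intensity)[2:3])
}

#' Replace bad detector elements by spatial neighbour means
#'
#' Each flagged (sample, band) element is replaced, on every scan line, by
#' the mean of its valid spatial neighbours (the 8-neighbourhood in the
#' line-sample plane) at the same band; neighbours that are themselves
#' flagged, or masked, are excluded. If no valid neighbour exists the element
#' stays masked. No other element changes.
#'
#' @param cube a \code{\link{Hypercube}}.
#' @param map a \code{\link{BadPixelMap}}.
#' @return corrected \code{\link{Hypercube}}.
#' @export
correctBadPixels <- function(cube, map) {
  stopifnot(is(cube, "Hypercube"), is(map, "BadPixelMap"))
  validObject(map)
  if (nrow(map@coords) == 0L) return(cube)
  d <- dim(cube@values)
  if (!all(map@detectorDim == d[2:3]))
    stop("bad-pixel map detector dimensions do not match the cube")
  v <- cube@values
  badByBand <- split(map@coords[, 1L], map@coords[, 2L])
  for (bandKey in names(badByBand)) {
    b <- as.integer(bandKey)
    plane <- v[, , b, drop = TRUE]
    if (is.null(dim(plane))) plane <- matrix(plane, nrow = d[1])
    badS <- badByBand[[bandKey]]
    src <- plane
    src[, badS] <- NA_real_  # flagged columns never contribute
    fixed <- plane
    for (s in badS) {
      for (l in seq_len(d[1])) {
        ln <- max(1L, l - 1L):min(d[1], l + 1L)
        sn <- max(1L, s - 1L):min(d[2], s + 1L)
        nb <- src[ln, sn]
        nb[ln == l, sn == s] <- NA_real_
        fixed[l, s] <- if (all(is.na(nb))) NA_real_ else mean(nb, na.rm = TRUE)
      }
    }
    v[, , b] <- fixed
  }
  new("Hypercube", values = v, wavelengths = cube@wavelengths, unit = cube@unit,
      metadata = c(cube@metadata, list(badPixelsCorrected = nrow(map@coords))))
}

#' @describeIn trimBands drop the first \code{nLeading} bands of a hypercube
#'   (the detector's initial bands are unusable due to sensor response).
#' @export
setMethod("trimBands", "Hypercube", function(cube, nLeading = 16L) {
  nLeading <- as.integer(nLeading)
  d <- dim(cube@values)
  if (nLeading >= d[3]) stop("cannot trim ", nLeading, " of ", d[3], " bands")
  if (nLeading == 0L) return(cube)
  keep <- (nLeading + 1L):d[3]
  new("Hypercube", values = cube@values[, , keep, drop = FALSE],
      wavelengths = cube@wavelengths[keep], unit = cube@unit,
      metadata = c(cube@metadata, list(trimLeadingBands = nLeading)))
})

#' @describeIn trimBands drop leading bands of a raw scan and its reference
#'   frames.
#' @export
setMethod("trimBands", "RawScan", function(cube, nLeading = 16L) {
  nLeading <- as.integer(nLeading)
  d <- dim(cube@intensity)
  if (nLeading >= d[3]) stop("cannot trim ", nLeading, " of ", d[3], " bands")
  if (nLeading == 0L) return(cube)
  keep <- (nLeading + 1L):d[3]
  new("RawScan", intensity = cube@intensity[, , keep, drop = FALSE],
      white = cube@white[, keep, drop = FALSE],
      darkSample = cube@darkSample[, keep, drop = FALSE],
      darkWhite = cube@darkWhite[, keep, drop = FALSE],
      exposureSample = cube@exposureSample, exposureWhite = cube@exposureWhite,
      wavelengths = cube@wavelengths[keep],
      metadata = c(cube@metadata, list(trimLeadingBands = nLeading)))
})
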