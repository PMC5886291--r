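# ENVI-style header + flat binary cube I/O. Header is plain key = value text
# with brace-enclosed lists; the cube is stored little-endian in one of the
# three standard interleaves (BIL/BIP/BSQ).

.enviDataTypes <- list(
  # ENVI code -> list(what, size, signed)
  `2`  = list(what = "integer", size = 2L, signed = TRUE),
  `4`  = list(what = "double",  size = 4L, signed = TRUE),
  `5`  = list(what = "double",  size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parseEnviHeader <- function(headerPath) {
  txt <- readLines(headerPath, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  fields <- list()
  # strip leading ENVI magic
  body <- sub("^\\s*ENVI\\s*", "", txt)
  # tokenise: key = scalar | key = { ... }
  pat <- "([A-Za-z][A-Za-z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, body, perl = TRUE)[[1]]
  if (m[1] == -1) stop("ENVI header has no key = value fields: ", headerPath)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(body, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    fields[[tolower(key)]] <- val
  }
  fields
}

.enviNumericList <- function(val) {
  val <- gsub("[{}]", "", val)
  as.numeric(trimws(strsplit(val, ",")[[1]]))
}

.enviRequire <- function(fields, key) {
  if (is.null(fields[[key]]))
    stop(sprintf("ENVI header is missing required field '%s'", key))
  fields[[key]]
}

#' Read an ENVI hypercube
#'
#' Reads an ENVI-style header (\code{.hdr}, key = value text) and its flat
#' binary cube. Supported interleaves are BIL, BIP and BSQ; supported data
#' types are 2 (int16), 4 (float32), 5 (float64) and 12 (uint16),
#' little-endian.
#'
#' @param headerPath path to the \code{.hdr} file. The binary cube is looked
#'   up next to it (same path without \code{.hdr}, or with \code{.raw}/
#'   \code{.dat} appended).
#' @return a \code{\link{Hypercube}}; the unit tag is taken from an optional
#'   \code{unit} header field and defaults to \code{"counts"}.
#' @seealso \code{\link{writeENVI}}
#' @export
readENVI <- function(headerPath) {
  if (!file.exists(headerPath)) stop("ENVI header not found: ", headerPath)
  f <- .parseEnviHeader(headerPath)
  ns <- as.integer(.enviRequire(f, "samples"))
  nl <- as.integer(.enviRequire(f, "lines"))
  nb <- as.integer(.enviRequire(f, "bands"))
  dt <- as.character(as.integer(.enviRequire(f, "data type")))
  il <- tolower(trimws(.enviRequire(f, "interleave")))
  if (!il %in% c("bil", "bip", "bsq"))
    stop("ENVI header field 'interleave' must be bil, bip or bsq, got: ", il)
  spec <- .enviDataTypes[[dt]]
  if (is.null(spec)) stop("unsupported ENVI 'data type': ", dt)
  byteOrder <- as.integer(f[["byte order"]] %||% "0")
  endian <- if (byteOrder == 0L) "little" else "big"

  base <- sub("\\.hdr$", "", headerPath)
  binPath <- c(base, paste0(base, ".raw"), paste0(base, ".dat"))
  binPath <- binPath[file.exists(binPath)][1]
  if (is.na(binPath)) stop("binary cube for header not found: ", headerPath)

  n <- ns * nl * nb
  con <- file(binPath, "rb")
  on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n, size = spec$size,
               signed = spec$signed, endian = endian)
  if (length(v) != n) stop("binary cube shorter than declared dimensions")

  cube <- switch(il,
    bsq = aperm(array(v, dim = c(ns, nl, nb)), c(2, 1, 3)),
    bil = aperm(array(v, dim = c(ns, nb, nl)), c(3, 1, 2)),
    bip = aperm(array(v, dim = c(nb, ns, nl)), c(3, 2, 1))
  )

  wl <- if (!is.null(f$wavelength)) .enviNumericList(f$wavelength) else seq_len(nb)
  if (length(wl) != nb)
    stop(sprintf("ENVI header field 'wavelength' has %d entries for %d bands",
                 length(wl), nb))
  unit <- f$unit %||% "counts"
  new("Hypercube", values = cube, wavelengths = wl, unit = unit,
      metadata = list(source = normalizePath(headerPath), interleave = il,
                      dataType = as.integer(dt)))
}

#' Write an ENVI hypercube
#'
#' @param cube a \code{\link{Hypercube}}.
#' @param basePath output path without extension; writes \code{basePath.hdr}
#'   and \code{basePath.raw}.
#' @param interleave \code{"bil"}, \code{"bip"} or \code{"bsq"}.
#' @param dataType ENVI data type code: 2, 4, 5 (default; lossless for double
#'   precision) or 12.
#' @return invisibly, the header path.
#' @export
writeENVI <- function(cube, basePath, interleave = "bil", dataType = 5L) {
  stopifnot(is(cube, "Hypercube"))
  interleave <- tolower(interleave)
  if (!interleave %in% c("bil", "bip", "bsq")) stop("unknown interleave: ", interleave)
  spec <- .enviDataTypes[[as.character(dataType)]]
  if (is.null(spec)) stop("unsupported ENVI 'data type': ", dataType)
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    paste0("data type = ", dataType),
    paste0("interleave = ", interleave),
    "byte order = 0",
    paste0("unit = ", cube@unit),
    "wavelength units = Nanometers",
    paste0("wavelength = { ",
           paste(format(cube@wavelengths, digits = 15, trim = TRUE), collapse = ", "),
           " }")
  )
  writeLines(hdr, paste0(basePath, ".hdr"))
  arr <- switch(interleave,
    bsq = aperm(cube@values, c(2, 1, 3)),
    bil = aperm(cube@values, c(2, 3, 1)),
    bip = aperm(cube@values, c(3, 2, 1))
  )
  v <- as.vector(arr)
  if (spec$what == "integer") v <- as.integer(round(v))
  con <- file(paste0(basePath, ".raw"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = spec$size, endian = "little")
  invisible(paste0(basePath, ".hdr"))
}

#' Assemble a raw scan from cube and reference frames
#'
#' @param intensity sample cube, lines x samples x bands (counts), or a
#'   \code{Hypercube} in counts.
#' @param white white-reference frame: samples x bands matrix, or a cube /
#'   counts \code{Hypercube} that is averaged over its scan lines.
#' @param darkSample,darkWhite dark frames (shutter closed) for the sample
#'   and white exposures; matrix, cube or counts \code{Hypercube} as above.
#' @param exposureSample,exposureWhite integration times, milliseconds.
#' @param wavelengths wavelength grid, nm; taken from \code{intensity} when
#'   it is a \code{Hypercube}.
#' @param metadata optional provenance list.
#' @return a \code{\link{RawScan}}.
#' @export
rawScan <- function(intensity, white, darkSample, darkWhite,
                    exposureSample, exposureWhite,
                    wavelengths = NULL, metadata = list()) {
  if (is(intensity, "Hypercube")) {
    wavelengths <- wavelengths %||% intensity@wavelengths
    intensity <- intensity@values
  }
  asFrame <- function(x) {
    if (is(x, "Hypercube")) x <- x@values
    if (length(dim(x)) == 3L) x <- apply(x, c(2, 3), mean)  # average scan lines
    x
  }
  new("RawScan", intensity = intensity, white = asFrame(white),
      darkSample = asFrame(darkSample), darkWhite = asFrame(darkWhite),
      exposureSample = exposureSample, exposureWhite = exposureWhite,
      wavelengths = wavelengths %||% seq_len(dim(intensity)[3]),
      metadata = metadata)
}

#' @describeIn wavelengths wavelengths of a hypercube
#' @export
setMethod("wavelengths", "Hypercube", function(x) x@wavelengths)

#' @describeIn wavelengths wavelengths of a raw scan
#' @export
setMethod("wavelengths", "RawScan", function(x) x@wavelengths)

#' @describeIn cubeValues values of a hypercube
#' @export
setMethod("cubeValues", "Hypercube", function(x) x@values)

#' @describeIn cubeValues detector counts of a raw scan
#' @export
setMethod("cubeValues", "RawScan", function(x) x@intensity)

#' @describeIn unitTag unit of a hypercube
#' @export
setMethod("unitTag", "Hypercube", function(x) x@unit)

setMethod("show", "Hypercube", function(object) {
  d <- dim(object@values)
  cat(sprintf("Hypercube: %d lines x %d samples x %d bands [%s]\n",
              d[1], d[2], d[3], object@unit))
  cat(sprintf("  wavelengths: %.1f - %.1f nm\n",
              min(object@wavelengths), max(object@wavelengths)))
  nmask <- sum(is.na(object@values))
  if (nmask > 0) cat(sprintf("  masked elements: %d\n", nmask))
})

setMethod("show", "RawScan", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("RawScan: %d lines x %d samples x %d bands (counts)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  exposures: sample %.3g ms, white %.3g ms\n",
              object@exposureSample, object@exposureWhite))
})
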