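#' Write a simulated scan as an on-disk fixture
#'
#' Writes the sample cube and the white/dark reference frames as ENVI
#' header + raw pairs, the ground-truth table as CSV and a JSON manifest
#' (seed, exposures, bad-pixel coordinates, generator parameters) so the
#' fixture is fully reproducible and loadable through the ENVI reader with
#' no side channel.
#'
#' @param sim result of \code{\link{simulateCube}} (or
#'   \code{\link{renderRawScan}}).
#' @param dir output directory (created if needed).
#' @param config the \code{\link{SimulationConfig}} used (recorded in the
#'   manifest).
#' @return invisibly, the manifest path.
#' @export
writeFixture <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scan <- sim$scan
  wl <- scan@wavelengths
  asCube <- function(m) {
    new("Hypercube", values = array(m, c(1L, nrow(m), ncol(m))),
        wavelengths = wl, unit = "counts", metadata = list())
  }
  writeENVI(new("Hypercube", values = scan@intensity, wavelengths = wl,
                unit = "counts", metadata = list()),
            file.path(dir, "scan"), interleave = "bil")
  writeENVI(asCube(scan@white), file.path(dir, "white"), interleave = "bil")
  writeENVI(asCube(scan@darkSample), file.path(dir, "dark_sample"), interleave = "bil")
  writeENVI(asCube(scan@darkWhite), file.path(dir, "dark_white"), interleave = "bil")
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  manifest <- list(
    exposureSample = scan@exposureSample,
    exposureWhite = scan@exposureWhite,
    seed = scan@metadata$seed,
    badPixels = if (nrow(sim$badPixels@coords)) sim$badPixels@coords else NULL,
    config = if (!is.null(config)) config@params else NULL)
  writeLines(jsonlite::toJSON(manifest, digits = NA, auto_unbox = TRUE,
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Read a fixture back into a raw scan
#'
#' @param dir directory written by \code{\link{writeFixture}}.
#' @return list: \code{scan} (a \code{\link{RawScan}}), \code{truth}
#'   (data.frame), \code{badPixels} (a \code{\link{BadPixelMap}}),
#'   \code{manifest} (list).
#' @export
readFixture <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyMatrix = TRUE)
  cube <- readENVI(file.path(dir, "scan.hdr"))
  frame <- function(name) {
    v <- cubeValues(readENVI(file.path(dir, paste0(name, ".hdr"))))
    matrix(v, dim(v)[2], dim(v)[3])
  }
  scan <- rawScan(cube, frame("white"), frame("dark_sample"), frame("dark_white"),
                  exposureSample = man$exposureSample,
                  exposureWhite = man$exposureWhite,
                  metadata = list(source = normalizePath(dir)))
  d <- dim(scan@intensity)
  bp <- if (!is.null(man$badPixels)) {
    badPixelMap(matrix(as.integer(unlist(man$badPixels)), ncol = 2L), d[2:3])
  } else badPixelMap(NULL, d[2:3])
  list(scan = scan,
       truth = read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE),
       badPixels = bp, manifest = man)
}

#' Run the full calibration-to-dataset pipeline on a raw scan
#'
#' The standard ingestion chain: reflectance calibration, bad-pixel
#' correction, absorbance, leading-band trim, segmentation and per-bean mean
#' spectra.
#'
#' @param scan a \code{\link{RawScan}}.
#' @param badPixels optional \code{\link{BadPixelMap}} (auto-detected from
#'   the scan when NULL).
#' @param trimLeading leading bands to drop (default 16).
#' @param minSize minimum object size for segmentation.
#' @param creaseExclusion logical; apply the crease-exclusion rule to every
#'   region before computing mean spectra.
#' @param side optional side tag.
#' @return list: \code{cube} (trimmed absorbance \code{\link{Hypercube}}),
#'   \code{segmentation} (\code{\link{SegmentationResult}}),
#'   \code{spectra} (beans x bands matrix of mean spectra).
#' @export
processScan <- function(scan, badPixels = NULL, trimLeading = 16L,
                        minSize = 50L, creaseExclusion = FALSE,
                        side = NA_character_) {
  refl <- calibrateReflectance(scan)
  if (is.null(badPixels)) badPixels <- detectBadPixels(scan)
  refl <- correctBadPixels(refl, badPixels)
  ab <- toAbsorbance(refl)
  ab <- trimBands(ab, trimLeading)
  seg <- segmentBeans(ab, minSize = minSize, side = side)
  if (creaseExclusion && length(seg@regions)) {
    regs <- lapply(seg@regions, function(r) excludeCrease(r, ab))
    lab <- seg@labelImage
    for (r in regs) { lab[r@creaseMask] <- 0L }
    seg <- new("SegmentationResult", labelImage = lab, regions = regs,
               parameters = c(seg@parameters, list(creaseExcluded = TRUE)))
  }
  spectra <- if (length(seg@regions)) {
    t(vapply(seg@regions, function(r) r@meanSpectrum,
             numeric(length(wavelengths(ab)))))
  } else matrix(numeric(), 0L, length(wavelengths(ab)))
  list(cube = ab, segmentation = seg, spectra = spectra)
}
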