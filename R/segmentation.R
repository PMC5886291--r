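#' Segment beans from the dark stage background
#'
#' Thresholds a scalar summary image (by default the mean absorbance across
#' bands) to separate beans from the near-black stage, bridges crease-split
#' halves with a small morphological closing, labels connected components,
#' drops specks below a minimum size and orders the surviving regions
#' row-major by centroid (top-left bean first) for reproducible numbering.
#'
#' On the dark stage the background reflects almost nothing, so its mean
#' absorbance is much higher than the beans'; the default therefore keeps the
#' low-absorbance side of the threshold as foreground.
#'
#' @param cube an absorbance \code{\link{Hypercube}}.
#' @param minSize minimum object size in pixels (default 50).
#' @param threshold fixed threshold on the summary image; default NULL uses
#'   Otsu's method.
#' @param foreground which side of the threshold is bean: \code{"low"}
#'   (default, mean absorbance below threshold) or \code{"high"}.
#' @param closingSize side of the square closing brush (default 3); 0
#'   disables.
#' @param side optional side tag (\code{"up"}/\code{"down"}) stamped on every
#'   region.
#' @return a \code{\link{SegmentationResult}}; zero found objects gives an
#'   empty result with a warning.
#' @export
segmentBeans <- function(cube, minSize = 50L, threshold = NULL,
                         foreground = c("low", "high"), closingSize = 3L,
                         side = NA_character_) {
  stopifnot(is(cube, "Hypercube"))
  if (cube@unit != "absorbance")
    stop("segmentBeans expects an absorbance cube, got unit '", cube@unit, "'")
  foreground <- match.arg(foreground)
  d <- dim(cube@values)
  M <- apply(cube@values, c(1, 2), mean, na.rm = TRUE)
  M[!is.finite(M)] <- NA_real_
  th <- threshold %||% otsuThreshold(M)
  fg <- if (foreground == "low") M < th else M > th
  fg[is.na(fg)] <- FALSE

  if (closingSize > 0L) {
    brush <- EBImage::makeBrush(as.integer(closingSize), shape = "box")
    fg <- EBImage::closing(EBImage::Image(fg * 1), brush) > 0.5
    fg <- matrix(as.vector(fg), nrow = d[1])
  }

  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow = d[1])

  counts <- table(lab[lab != 0L])
  keep <- as.integer(names(counts)[counts >= minSize])
  lab[!(lab %in% keep)] <- 0L

  params <- list(minSize = as.integer(minSize), threshold = th,
                 foreground = foreground, closingSize = as.integer(closingSize))
  if (length(keep) == 0L) {
    warning("no objects found above the minimum size")
    return(new("SegmentationResult", labelImage = lab, regions = list(),
               parameters = params))
  }

  cent <- t(vapply(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))

  # row-major ordering: cluster centroid lines into rows, then sort by sample
  ord <- order(cent[, 1])
  heights <- vapply(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE); diff(range(w[, 1])) + 1
  }, numeric(1))
  gap <- median(heights) / 2
  rowId <- integer(length(keep))
  cur <- 1L; rowId[ord[1]] <- 1L
  if (length(keep) > 1L) for (i in 2:length(keep)) {
    if (cent[ord[i], 1] - cent[ord[i - 1], 1] > gap) cur <- cur + 1L
    rowId[ord[i]] <- cur
  }
  finalOrd <- order(rowId, cent[, 2])

  relab <- matrix(0L, d[1], d[2])
  regions <- vector("list", length(keep))
  for (i in seq_along(finalOrd)) {
    k <- keep[finalOrd[i]]
    m <- lab == k
    relab[m] <- i
    regions[[i]] <- new("BeanRegion", label = i, mask = m,
                        pixelCount = sum(m),
                        centroid = cent[finalOrd[i], ],
                        meanSpectrum = .maskMean(cube@values, m),
                        side = side,
                        creaseMask = matrix(FALSE, d[1], d[2]))
  }
  new("SegmentationResult", labelImage = relab, regions = regions,
      parameters = params)
}

.maskMean <- function(values, mask) {
  idx <- which(mask)
  colMeans(pixelMatrix(values, idx), na.rm = TRUE)
}

#' Mean spectrum of a bean region
#'
#' Unweighted per-band mean over the region's unmasked pixels; NA elements
#' are ignored band-wise.
#'
#' @param region a \code{\link{BeanRegion}}.
#' @param cube the \code{\link{Hypercube}} the region was segmented from.
#' @return numeric vector, one value per band.
#' @export
meanSpectrum <- function(region, cube) {
  stopifnot(is(region, "BeanRegion"), is(cube, "Hypercube"))
  if (region@pixelCount == 0L) stop("region mask is empty")
  .maskMean(cube@values, region@mask)
}

#' Exclude the midline crease from a bean region
#'
#' The crease (mesenteric root) runs along the bean's central axis and its
#' topography distorts reflectance, biasing the bean's mean spectrum. Pixels
#' lying near the major axis whose spectra deviate beyond a z-score threshold
#' from the bean's band-wise median spectrum are removed from the mask before
#' mean-spectrum computation. The exact exclusion rule used on the original
#' instrument software is not documented; this z-score rule is this package's
#' stated stand-in. Exclusion is capped at a fraction of the bean's pixels
#' (most-deviant pixels kept excluded first).
#'
#' @param region a \code{\link{BeanRegion}}.
#' @param cube the absorbance \code{\link{Hypercube}}.
#' @param zMax z-score threshold (default 3).
#' @param axisFrac half-width of the central-axis band as a fraction of the
#'   bean's minor-axis extent (default 0.3).
#' @param capFrac maximum fraction of bean pixels that may be excluded
#'   (default 0.2).
#' @return the region with crease pixels removed from \code{mask}, recorded
#'   in \code{creaseMask}, and \code{meanSpectrum}/\code{pixelCount}
#'   recomputed.
#' @export
excludeCrease <- function(region, cube, zMax = 3, axisFrac = 0.3, capFrac = 0.2) {
  stopifnot(is(region, "BeanRegion"), is(cube, "Hypercube"))
  idx <- which(region@mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 10L) return(region)
  X <- pixelMatrix(cube@values, which(region@mask))

  # principal axes of the pixel cloud
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  ev <- eigen(crossprod(cc) / n, symmetric = TRUE)
  minorDist <- abs(cc %*% ev$vectors[, 2])
  nearAxis <- minorDist <= axisFrac * max(minorDist)

  med <- apply(X, 2, median, na.rm = TRUE)
  # robust band-wise scale so the crease pixels do not inflate their own
  # deviation denominator
  s <- apply(X, 2, mad, na.rm = TRUE)
  s[!is.finite(s) | s < 1e-12] <- 1e-12
  z <- rowMeans(sweep(sweep(X, 2, med), 2, s, "/"), na.rm = TRUE)

  candidate <- nearAxis & abs(z) > zMax
  cap <- floor(capFrac * n)
  if (sum(candidate) > cap) {
    ordExtreme <- order(abs(z), decreasing = TRUE)
    allowed <- ordExtreme[ordExtreme %in% which(candidate)][seq_len(cap)]
    candidate <- rep(FALSE, n)
    candidate[allowed] <- TRUE
  }
  if (!any(candidate)) return(region)

  mask <- region@mask
  crease <- matrix(FALSE, nrow(mask), ncol(mask))
  drop <- which(region@mask)[candidate]
  mask[drop] <- FALSE
  crease[drop] <- TRUE
  w <- which(mask, arr.ind = TRUE)
  new("BeanRegion", label = region@label, mask = mask,
      pixelCount = sum(mask), centroid = c(mean(w[, 1]), mean(w[, 2])),
      meanSpectrum = .maskMean(cube@values, mask), side = region@side,
      creaseMask = crease)
}

#' Pair beans scanned on both surfaces
#'
#' Beans are scanned once, manually rotated, and scanned again; the two
#' segmentations are matched by rank of scan position (the row-major region
#' order), optionally reversed when the tray was re-laid in opposite order.
#' Per-bean two-side average spectra are returned.
#'
#' @param up,down \code{\link{SegmentationResult}}s for the two surfaces.
#' @param reversed logical; TRUE matches the first up-bean with the last
#'   down-bean.
#' @param pairing optional explicit integer vector: \code{pairing[i]} is the
#'   down-region index matched to up-region i. Required when the object
#'   counts differ.
#' @return list with \code{pairs} (data.frame: bean, labelUp, labelDown) and
#'   \code{spectra} (beans x bands matrix of two-side average spectra).
#' @export
pairSides <- function(up, down, reversed = FALSE, pairing = NULL) {
  nu <- length(up@regions); nd <- length(down@regions)
  if (is.null(pairing)) {
    if (nu != nd)
      stop(sprintf("object counts differ (%d up vs %d down); supply an explicit pairing", nu, nd))
    pairing <- if (reversed) rev(seq_len(nd)) else seq_len(nd)
  }
  if (length(pairing) != nu || anyDuplicated(pairing) || any(pairing < 1L | pairing > nd))
    stop("pairing must be a permutation matching every up-region to a down-region")
  spec <- t(vapply(seq_len(nu), function(i) {
    (up@regions[[i]]@meanSpectrum + down@regions[[pairing[i]]]@meanSpectrum) / 2
  }, numeric(length(up@regions[[1]]@meanSpectrum))))
  list(pairs = data.frame(bean = seq_len(nu),
                          labelUp = seq_len(nu),
                          labelDown = as.integer(pairing)),
       spectra = spec)
}

#' @describeIn beanRegions regions of a segmentation
#' @export
setMethod("beanRegions", "SegmentationResult", function(x) x@regions)

#' @describeIn labelImage label image of a segmentation
#' @export
setMethod("labelImage", "SegmentationResult", function(x) x@labelImage)

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d region(s)\n", length(object@regions)))
  for (r in object@regions)
    cat(sprintf("  bean %d: %d px, centroid (%.1f, %.1f)%s\n", r@label,
                r@pixelCount, r@centroid[1], r@centroid[2],
                if (is.na(r@side)) "" else paste0(" [", r@side, "]")))
})

#' Write segmentation artefacts
#'
#' Writes the label image as a 16-bit grey PNG, the region table as CSV
#' (label, side, pixels, centroid_line, centroid_sample) and the mean spectra
#' as CSV with a wavelength header row.
#'
#' @param seg a \code{\link{SegmentationResult}}.
#' @param cube the source \code{\link{Hypercube}} (for wavelengths).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeSegmentation <- function(seg, cube, dir, prefix = "segmentation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pngPath <- file.path(dir, paste0(prefix, "_labels.png"))
  png::writePNG(t(seg@labelImage) / 65535, pngPath)  # 16-bit grey
  tab <- do.call(rbind, lapply(seg@regions, function(r)
    data.frame(label = r@label, side = r@side, pixels = r@pixelCount,
               centroid_line = r@centroid[1], centroid_sample = r@centroid[2])))
  tabPath <- file.path(dir, paste0(prefix, "_regions.csv"))
  write.csv(tab, tabPath, row.names = FALSE)
  spec <- t(vapply(seg@regions, function(r) r@meanSpectrum,
                   numeric(length(wavelengths(cube)))))
  colnames(spec) <- format(wavelengths(cube), trim = TRUE)
  specPath <- file.path(dir, paste0(prefix, "_mean_spectra.csv"))
  write.csv(data.frame(label = vapply(seg@regions, function(r) r@label, integer(1)),
                       spec, check.names = FALSE),
            specPath, row.names = FALSE)
  invisible(c(pngPath, tabPath, specPath))
}
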