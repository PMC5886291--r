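#' Predict an analyte concentration for every bean pixel
#'
#' Applies a trained calibration to each segmented bean pixel: the pixel's
#' absorbance spectrum passes through the model's stored pre-treatment chain
#' (applied per pixel spectrum, the only interpretation consistent with
#' single-pixel-level mapping) and then the collapsed regression
#' coefficients. Background pixels carry no value. Crease pixels, when the
#' segmentation recorded them, are predicted but flagged - they were excluded
#' only from calibration, not from mapping.
#'
#' @param cube an absorbance \code{\link{Hypercube}}, trimmed to the model's
#'   wavelength grid.
#' @param seg a \code{\link{SegmentationResult}} for the same cube.
#' @param model a \code{\link{PLSModel}}.
#' @param moisture optional moisture for dry-weight conversion of the pixel
#'   predictions: a scalar batch fraction, or a per-pixel matrix.
#' @return a \code{\link{ChemicalImage}}; its per-bean table records both the
#'   mean of the pixel predictions and the prediction on the bean's mean
#'   spectrum.
#' @export
predictPixels <- function(cube, seg, model, moisture = NULL) {
  stopifnot(is(cube, "Hypercube"), is(seg, "SegmentationResult"),
            is(model, "PLSModel"))
  if (cube@unit != "absorbance") stop("predictPixels expects an absorbance cube")
  wl <- cube@wavelengths
  if (length(wl) != length(model@wavelengths) ||
      max(abs(wl - model@wavelengths)) > 1e-6)
    stop(sprintf(
      "wavelength grid mismatch: model expects %d bands %.1f-%.1f nm, cube has %d bands %.1f-%.1f nm",
      length(model@wavelengths), min(model@wavelengths), max(model@wavelengths),
      length(wl), min(wl), max(wl)))
  d <- dim(cube@values)
  map <- matrix(NA_real_, d[1], d[2])
  crease <- matrix(FALSE, d[1], d[2])
  perBean <- vector("list", length(seg@regions))
  for (i in seq_along(seg@regions)) {
    r <- seg@regions[[i]]
    full <- r@mask | r@creaseMask   # crease pixels are predicted, then flagged
    idx <- which(full)
    P <- pixelMatrix(cube@values, idx)
    pred <- predict(model, P)
    map[idx] <- pred
    crease <- crease | r@creaseMask
    if (!is.null(moisture)) {
      mo <- if (is.matrix(moisture)) moisture[idx] else moisture
      map[idx] <- toDryBasis(map[idx], mo)
      pred <- map[idx]
    }
    calib <- map[which(r@mask)]     # crease excluded, as in calibration
    perBean[[i]] <- data.frame(
      label = r@label, nPixels = length(idx),
      pixelMean = mean(pred), pixelSD = sd(pred),
      meanSpecPred = {
        msPred <- predict(model, r@meanSpectrum)
        if (!is.null(moisture) && !is.matrix(moisture))
          msPred <- toDryBasis(msPred, moisture)
        msPred
      },
      maskedPixelMean = mean(calib, na.rm = TRUE))
  }
  perBean <- if (length(perBean)) do.call(rbind, perBean) else
    data.frame(label = integer(), nPixels = integer(), pixelMean = numeric(),
               pixelSD = numeric(), meanSpecPred = numeric(),
               maskedPixelMean = numeric())
  vals <- map[!is.na(map)]
  bounds <- if (length(vals)) as.numeric(quantile(vals, c(0.01, 0.99))) else c(NA_real_, NA_real_)
  lab <- seg@labelImage
  for (r in seg@regions) lab[r@creaseMask] <- r@label
  new("ChemicalImage", map = map, analyte = model@analyte,
      basis = if (is.null(moisture)) model@basis else "dwb",
      labelImage = lab, perBean = perBean, bounds = bounds,
      creaseFlag = crease)
}

#' Per-bean summary of a chemical image
#'
#' @param image a \code{\link{ChemicalImage}}.
#' @param reference optional data.frame with columns \code{label} and
#'   \code{reference} (mg/g); when supplied, residuals (predicted minus
#'   reference) are added.
#' @return data.frame: label, nPixels, predicted (pixel mean), pixelSD
#'   (within-bean heterogeneity), meanSpecPred, and with a reference table
#'   also reference and residual.
#' @export
perBeanSummary <- function(image, reference = NULL) {
  out <- data.frame(label = image@perBean$label,
                    nPixels = image@perBean$nPixels,
                    predicted = image@perBean$pixelMean,
                    pixelSD = image@perBean$pixelSD,
                    meanSpecPred = image@perBean$meanSpecPred)
  if (!is.null(reference)) {
    stopifnot(all(c("label", "reference") %in% colnames(reference)))
    out$reference <- reference$reference[match(out$label, reference$label)]
    out$residual <- out$predicted - out$reference
  }
  out
}

#' @describeIn labelImage bean labels of a chemical image
#' @export
setMethod("labelImage", "ChemicalImage", function(x) x@labelImage)

setMethod("show", "ChemicalImage", function(object) {
  cat(sprintf("ChemicalImage: %s (%s), %d bean(s), %d predicted pixel(s)\n",
              object@analyte, object@basis, nrow(object@perBean),
              sum(!is.na(object@map))))
  if (nrow(object@perBean))
    cat(sprintf("  per-bean means: %s mg/g\n",
                paste(sprintf("%.1f", object@perBean$pixelMean), collapse = ", ")))
})

#' Render a chemical image to disk
#'
#' Writes a false-colour PNG with a colour bar and per-bean annotation
#' (predicted mean, and the reference value when supplied), plus the numeric
#' map saved losslessly as TSV (NA = background).
#'
#' @param image a \code{\link{ChemicalImage}}.
#' @param path output PNG path; the numeric map goes to the same path with
#'   extension \code{.tsv}.
#' @param seg optional \code{\link{SegmentationResult}} for annotation
#'   placement (centroids); defaults to label-image centroids.
#' @param reference optional reference table as in
#'   \code{\link{perBeanSummary}}.
#' @param bounds colour-scale bounds; default the image's stored 1st-99th
#'   percentile bounds.
#' @return invisibly, c(pngPath, tsvPath).
#' @export
renderMap <- function(image, path, seg = NULL, reference = NULL, bounds = NULL) {
  bounds <- bounds %||% image@bounds
  tsvPath <- sub("\\.png$", ".tsv", path)
  if (identical(tsvPath, path)) tsvPath <- paste0(path, ".tsv")
  write.table(image@map, tsvPath, sep = "\t", row.names = FALSE, col.names = FALSE)

  m <- image@map
  d <- dim(m)
  summ <- perBeanSummary(image, reference)
  grDevices::png(path, width = max(480L, d[2] * 3L + 140L),
                 height = max(360L, d[1] * 3L))
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(6, 1))
  graphics::par(mar = c(2, 2, 2, 1))
  pal <- grDevices::hcl.colors(256, "viridis")
  mm <- pmin(pmax(m, bounds[1]), bounds[2])
  graphics::image(x = seq_len(d[2]), y = seq_len(d[1]),
                  z = t(mm[d[1]:1, , drop = FALSE]),
                  zlim = bounds, col = pal, asp = 1, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%s (mg/g, %s)", image@analyte, image@basis))
  cent <- if (!is.null(seg)) {
    t(vapply(seg@regions, function(r) r@centroid, numeric(2)))
  } else {
    t(vapply(summ$label, function(k) {
      w <- which(image@labelImage == k, arr.ind = TRUE)
      c(mean(w[, 1]), mean(w[, 2]))
    }, numeric(2)))
  }
  for (i in seq_len(nrow(summ))) {
    lab <- sprintf("%.1f", summ$predicted[i])
    if (!is.null(reference) && !is.na(summ$reference[i]))
      lab <- paste0(lab, "\n(", sprintf("%.1f", summ$reference[i]), ")")
    graphics::text(cent[i, 2], d[1] + 1 - cent[i, 1], lab, col = "white", cex = 0.8)
  }
  graphics::par(mar = c(2, 1, 2, 3))
  graphics::image(x = 1, y = seq(bounds[1], bounds[2], length.out = 256),
                  z = matrix(seq(bounds[1], bounds[2], length.out = 256), 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  invisible(c(path, tsvPath))
}

#' Read back a numeric map written by renderMap
#'
#' @param tsvPath the \code{.tsv} path.
#' @return numeric matrix with NA background.
#' @export
readMap <- function(tsvPath) {
  as.matrix(read.table(tsvPath, sep = "\t", header = FALSE))
}
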