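#' Synthetic study configuration
#'
#' Builds a \code{\link{SimulationConfig}} whose defaults emulate the study
#' conditions: ten beans per cube on a near-black stage, a 256-band
#' 980-2500 nm grid with the first 16 bands unusable, per-species
#' concentration statistics (mg/g, "as is": Arabica sucrose 46.7 +/- 7.5,
#' caffeine 15.7 +/- 2.3, trigonelline 8.6 +/- 1.8; Robusta 33.6 +/- 9.1,
#' 19.9 +/- 4.9, 7.3 +/- 1.7), inter-analyte correlations (sucrose-caffeine
#' -0.445, sucrose-trigonelline 0.395, caffeine-trigonelline -0.185),
#' truncation to the pooled observed ranges, bean-level multiplicative
#' scatter and additive band-wise detector noise. Any parameter can be
#' overridden by name. A correlation matrix that is not positive
#' semi-definite is repaired by eigenvalue clipping.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a \code{\link{SimulationConfig}}.
#' @section Parameters:
#' \describe{
#'   \item{beansPerCube}{objects per scene (10).}
#'   \item{lines, samples}{scene size in pixels (96 x 320).}
#'   \item{nBands, wavelengthRange, trimLeading}{256 bands over 980-2500 nm;
#'     16 leading sensor-roll-off bands.}
#'   \item{speciesMix}{named proportions, c(arabica = 0.5, robusta = 0.5).}
#'   \item{concMeans, concSDs}{2 x 3 matrices (species x analyte), mg/g.}
#'   \item{corrMatrix}{3 x 3 inter-analyte correlation target.}
#'   \item{concRanges}{3 x 2 truncation bounds (pooled observed min/max).}
#'   \item{gradientAmplitude}{relative within-bean linear gradient (0.05).}
#'   \item{scatterSlopeSD, scatterOffsetSD}{bean-level multiplicative /
#'     additive scatter SDs (0.05, 0.02 au).}
#'   \item{noiseSD}{additive band-wise pixel noise SD, absorbance units
#'     (0.01).}
#'   \item{leadingNoiseSD}{extra noise on the unusable leading bands (0.3).}
#'   \item{creaseStripe, creaseDepth}{midline stripe toggle (FALSE) and its
#'     added absorbance (0.3 au).}
#'   \item{badPixelCount}{dead detector elements injected (3).}
#'   \item{exposureSample, exposureWhite}{integration times, ms (4, 2).}
#'   \item{whiteLevel, darkLevel}{white / dark reference count levels
#'     (9000, 100).}
#'   \item{stageAbsorbance}{mean absorbance of the dark stage (1.2 au).}
#'   \item{moistureMean, moistureSD}{per-bean moisture fraction (0.094,
#'     0.01), matching the as-is/dry-basis mean ratio of the reference
#'     statistics.}
#'   \item{truncationCap}{rejection-sampling cap per bean (1000).}
#' }
#' @export
simulationConfig <- function(...) {
  analytes <- c("sucrose", "caffeine", "trigonelline")
  corr <- matrix(c(1, -0.445, 0.395,
                   -0.445, 1, -0.185,
                   0.395, -0.185, 1), 3, 3,
                 dimnames = list(analytes, analytes))
  p <- list(
    beansPerCube = 10L,
    lines = 96L, samples = 320L,
    nBands = 256L, wavelengthRange = c(980, 2500), trimLeading = 16L,
    speciesMix = c(arabica = 0.5, robusta = 0.5),
    concMeans = matrix(c(46.7, 15.7, 8.6,
                         33.6, 19.9, 7.3), 2, 3, byrow = TRUE,
                       dimnames = list(c("arabica", "robusta"), analytes)),
    concSDs = matrix(c(7.5, 2.3, 1.8,
                       9.1, 4.9, 1.7), 2, 3, byrow = TRUE,
                     dimnames = list(c("arabica", "robusta"), analytes)),
    corrMatrix = corr,
    concRanges = matrix(c(5.3, 70.8,
                          9.2, 31.9,
                          3.9, 15.0), 3, 2, byrow = TRUE,
                        dimnames = list(analytes, c("min", "max"))),
    gradientAmplitude = 0.05,
    scatterSlopeSD = 0.05, scatterOffsetSD = 0.02,
    noiseSD = 0.01, leadingNoiseSD = 0.3,
    creaseStripe = FALSE, creaseDepth = 0.3,
    badPixelCount = 3L,
    exposureSample = 4, exposureWhite = 2,
    whiteLevel = 9000, darkLevel = 100,
    stageAbsorbance = 1.2,
    moistureMean = 0.094, moistureSD = 0.01,
    truncationCap = 1000L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  # nearest-PSD repair by eigenvalue clipping
  ev <- eigen(p$corrMatrix, symmetric = TRUE)
  if (min(ev$values) < 0) {
    lam <- pmax(ev$values, 1e-8)
    m <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    d <- sqrt(diag(m))
    p$corrMatrix <- m / outer(d, d)
    dimnames(p$corrMatrix) <- dimnames(corr)
  }
  new("SimulationConfig", params = p)
}

setMethod("show", "SimulationConfig", function(object) {
  p <- object@params
  cat(sprintf("SimulationConfig: %d beans, %d x %d px, %d bands, noise SD %.3g au\n",
              p$beansPerCube, p$lines, p$samples, p$nBands, p$noiseSD))
})

.instrumentWavelengths <- function(config) {
  p <- config@params
  seq(p$wavelengthRange[1], p$wavelengthRange[2], length.out = p$nBands)
}

#' Draw correlated per-bean concentrations
#'
#' Species are assigned by the configured mix; per species, (sucrose,
#' caffeine, trigonelline) are drawn from a multivariate normal with the
#' species means/SDs and the common target correlation matrix, then
#' truncated by rejection to the pooled observed ranges (beans exceeding the
#' resample cap are clamped). Per-bean moisture fractions are drawn
#' alongside for dry-weight-basis work.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param nBeans number of beans.
#' @param seed RNG seed.
#' @return data.frame: bean, species, sucrose, caffeine, trigonelline,
#'   moisture (all concentrations mg/g "as is").
#' @export
sampleConcentrations <- function(config, nBeans, seed = 1L) {
  p <- config@params
  withSeed(seed, {
    species <- sample(names(p$speciesMix), nBeans, replace = TRUE,
                      prob = p$speciesMix)
    out <- matrix(NA_real_, nBeans, 3,
                  dimnames = list(NULL, rownames(p$concRanges)))
    for (i in seq_len(nBeans)) {
      mu <- p$concMeans[species[i], ]
      sdv <- p$concSDs[species[i], ]
      Sigma <- diag(sdv) %*% p$corrMatrix %*% diag(sdv)
      for (try in seq_len(p$truncationCap)) {
        x <- as.vector(MASS::mvrnorm(1, mu, Sigma))
        if (all(x >= p$concRanges[, "min"] & x <= p$concRanges[, "max"])) break
      }
      out[i, ] <- pmin(pmax(x, p$concRanges[, "min"]), p$concRanges[, "max"])
    }
    moisture <- pmin(pmax(rnorm(nBeans, p$moistureMean, p$moistureSD), 0.02), 0.2)
    data.frame(bean = seq_len(nBeans), species = species,
               as.data.frame(out), moisture = moisture)
  })
}

#' Lay out bean-shaped objects on the stage
#'
#' Places non-overlapping ellipses on a row-major grid with small jittered
#' centres and semi-axes, builds per-pixel concentration fields (bean
#' concentration modulated by an optional linear gradient along the major
#' axis) and, when enabled, a midline crease stripe along each bean's major
#' axis.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param concentrations table from \code{\link{sampleConcentrations}}.
#' @param seed RNG seed.
#' @return list: \code{labels} (integer lines x samples ground-truth mask
#'   image), \code{fields} (named list of three lines x samples
#'   concentration matrices), \code{crease} (logical matrix),
#'   \code{concentrations} (the input table).
#' @export
buildScene <- function(config, concentrations, seed = 1L) {
  p <- config@params
  n <- nrow(concentrations)
  nc <- min(5L, n)
  nr <- ceiling(n / nc)
  cellW <- p$samples / nc
  cellH <- p$lines / nr
  labels <- matrix(0L, p$lines, p$samples)
  crease <- matrix(FALSE, p$lines, p$samples)
  fields <- lapply(1:3, function(i) matrix(0, p$lines, p$samples))
  names(fields) <- rownames(p$concRanges)
  lineIdx <- matrix(seq_len(p$lines), p$lines, p$samples)
  sampIdx <- matrix(seq_len(p$samples), p$lines, p$samples, byrow = TRUE)
  withSeed(seed, {
    for (i in seq_len(n)) {
      row <- (i - 1L) %/% nc
      col <- (i - 1L) %% nc
      cy <- (row + 0.5) * cellH + runif(1, -0.05, 0.05) * cellH
      cx <- (col + 0.5) * cellW + runif(1, -0.05, 0.05) * cellW
      a <- 0.30 * cellW * runif(1, 0.9, 1.1)   # semi-axis, sample direction
      b <- 0.30 * cellH * runif(1, 0.9, 1.1)   # semi-axis, line direction
      theta <- runif(1, -0.15, 0.15)
      dl <- lineIdx - cy
      ds <- sampIdx - cx
      u <- (cos(theta) * ds + sin(theta) * dl) / a   # along major axis
      v <- (-sin(theta) * ds + cos(theta) * dl) / b  # along minor axis
      inside <- u^2 + v^2 <= 1
      labels[inside] <- i
      grad <- 1 + p$gradientAmplitude * u[inside]
      for (an in names(fields))
        fields[[an]][inside] <- concentrations[[an]][i] * grad
      if (p$creaseStripe)
        crease[inside & abs(v * b) <= 1.2] <- TRUE
    }
  })
  list(labels = labels, fields = fields, crease = crease,
       concentrations = concentrations)
}

#' Render a scene into a raw detector scan
#'
#' Builds per-pixel absorbance as matrix spectrum + sum of
#' concentration-scaled component spectra, applies bean-level multiplicative
#' scatter (slope, offset), the crease stripe, band-wise Gaussian noise and
#' heavy noise on the unusable leading bands; then inverts the absorbance
#' and reflectance calibration equations to produce detector counts with
#' the configured white/dark references and exposure times, and injects dead
#' detector elements.
#'
#' @param scene from \code{\link{buildScene}}.
#' @param library a \code{\link{ComponentLibrary}} on the full instrument
#'   grid.
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed RNG seed.
#' @param keepAbsorbance return the noise-free constructed absorbance cube
#'   (for round-trip checks); default FALSE.
#' @return list: \code{scan} (a \code{\link{RawScan}}), \code{truth} (the
#'   concentration table), \code{badPixels} (a \code{\link{BadPixelMap}}),
#'   and optionally \code{absorbance}.
#' @export
renderRawScan <- function(scene, library, config, seed = 1L,
                          keepAbsorbance = FALSE) {
  p <- config@params
  wl <- wavelengths(library)
  nb <- length(wl)
  nl <- p$lines; ns <- p$samples
  npx <- nl * ns
  comp <- library@spectra

  A <- matrix(0, npx, nb)
  bg <- scene$labels == 0L
  stage <- p$stageAbsorbance + 5e-5 * (wl - mean(wl))
  A[which(bg), ] <- matrix(stage, sum(bg), nb, byrow = TRUE)

  withSeed(seed, {
    for (i in sort(unique(scene$labels[scene$labels != 0L]))) {
      idx <- which(scene$labels == i)
      clean <- matrix(comp[, "matrix"], length(idx), nb, byrow = TRUE)
      for (an in names(scene$fields))
        clean <- clean + outer(scene$fields[[an]][idx], comp[, an])
      slope <- 1 + rnorm(1, 0, p$scatterSlopeSD)
      offset <- rnorm(1, 0, p$scatterOffsetSD)
      A[idx, ] <- slope * clean + offset
    }
    if (p$creaseStripe && any(scene$crease))
      A[which(scene$crease), ] <- A[which(scene$crease), ] + p$creaseDepth

    cleanA <- if (keepAbsorbance) A else NULL
    if (p$noiseSD > 0)
      A <- A + matrix(rnorm(npx * nb, 0, p$noiseSD), npx, nb)
    nLead <- p$trimLeading
    if (nLead > 0L && p$leadingNoiseSD > 0)
      A[, seq_len(nLead)] <- A[, seq_len(nLead)] +
        matrix(rnorm(npx * nLead, 0, p$leadingNoiseSD), npx, nLead)

    # invert Eq. 2 then Eq. 1 into counts
    R <- 10^(-A)
    white <- matrix(p$whiteLevel, ns, nb)
    white <- white * (0.92 + 0.16 * exp(-0.5 * ((wl - 1600) / 700)^2))[col(white)]
    white <- white * (1 + 0.01 * sin(seq_len(ns) / 17))[row(white)]
    darkS <- matrix(p$darkLevel, ns, nb)
    darkW <- matrix(p$darkLevel, ns, nb)
    gain <- p$exposureSample / p$exposureWhite
    I <- array(NA_real_, c(nl, ns, nb))
    for (b in seq_len(nb)) {
      Rb <- matrix(R[, b], nl, ns)
      I[, , b] <- Rb * matrix(white[, b] - darkW[, b], nl, ns, byrow = TRUE) * gain +
        matrix(darkS[, b], nl, ns, byrow = TRUE)
    }

    bp <- if (p$badPixelCount > 0L) {
      cbind(sample = sample.int(ns, p$badPixelCount, replace = TRUE),
            band = sample((p$trimLeading + 1L):nb, p$badPixelCount, replace = TRUE))
    } else matrix(integer(), ncol = 2L)
    for (j in seq_len(nrow(bp))) I[, bp[j, 1], bp[j, 2]] <- p$darkLevel

    out <- list(
      scan = rawScan(I, white, darkS, darkW,
                     exposureSample = p$exposureSample,
                     exposureWhite = p$exposureWhite,
                     wavelengths = wl,
                     metadata = list(synthetic = TRUE, seed = as.integer(seed))),
      truth = scene$concentrations,
      badPixels = badPixelMap(bp, c(ns, nb)))
    if (keepAbsorbance)
      out$absorbance <- array(cleanA, c(nl, ns, nb))
    out
  })
}

#' Simulate one ground-truthed cube
#'
#' Convenience wrapper: sample concentrations, build the scene, render the
#' raw scan. Sub-seeds are derived deterministically from \code{seed}.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @param seed RNG seed.
#' @param keepAbsorbance as in \code{\link{renderRawScan}}.
#' @return list: \code{scan}, \code{truth}, \code{scene}, \code{badPixels},
#'   optionally \code{absorbance}.
#' @export
simulateCube <- function(config, seed = 1L, keepAbsorbance = FALSE) {
  p <- config@params
  seed <- as.integer(seed)
  conc <- sampleConcentrations(config, p$beansPerCube, seed = seed)
  scene <- buildScene(config, conc, seed = seed + 1L)
  lib <- componentLibrary(.instrumentWavelengths(config))
  out <- renderRawScan(scene, lib, config, seed = seed + 2L,
                       keepAbsorbance = keepAbsorbance)
  out$scene <- scene
  out
}
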