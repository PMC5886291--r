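.gauss <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

#' Build a synthetic pure-component absorbance library
#'
#' Constructs Gaussian-peak absorbance profiles at each compound's known SWIR
#' absorption features: caffeine at 1668, 2250 and 2425 nm; trigonelline at
#' 1668 and 2269 nm; sucrose across the 1460-1700 nm region with a major
#' band near 2070 nm; and a bulk seed-matrix profile with water/carbohydrate
#' and lipid bands at 1430, 1930, 1730/1760 and 2250 nm. These are synthetic
#' constructions, not measured pure spectra: recovery testing needs only the
#' linear-mixture structure, peak placement and realistic band overlap (the
#' shared 1668 nm feature of caffeine and trigonelline included).
#'
#' Analyte columns are scaled to unit absorbance per mg/g so that pixel
#' spectra are built as matrix + sum(concentration x component).
#'
#' @param wavelengths wavelength grid, nm.
#' @param unitAbsorbance named per-mg/g scale factors for the three analytes.
#' @return a \code{\link{ComponentLibrary}}.
#' @export
componentLibrary <- function(wavelengths,
                             unitAbsorbance = c(sucrose = 1.2e-3,
                                                caffeine = 3.0e-3,
                                                trigonelline = 3.0e-3)) {
  wl <- wavelengths
  sucrose <- .gauss(wl, 1580, 110, 0.55) + .gauss(wl, 2070, 45, 1.0) +
    .gauss(wl, 1460, 40, 0.35)
  caffeine <- .gauss(wl, 1668, 28, 1.0) + .gauss(wl, 2250, 38, 0.8) +
    .gauss(wl, 2425, 38, 0.6)
  trigonelline <- .gauss(wl, 1668, 30, 0.9) + .gauss(wl, 2269, 40, 0.8)
  matrixSpec <- 0.35 + 1e-5 * (wl - 980) +
    .gauss(wl, 1430, 60, 0.45) + .gauss(wl, 1930, 55, 0.5) +
    .gauss(wl, 1730, 18, 0.10) + .gauss(wl, 1760, 18, 0.08) +
    .gauss(wl, 2250, 50, 0.18)
  sp <- cbind(sucrose = sucrose * unitAbsorbance[["sucrose"]],
              caffeine = caffeine * unitAbsorbance[["caffeine"]],
              trigonelline = trigonelline * unitAbsorbance[["trigonelline"]],
              matrix = matrixSpec)
  new("ComponentLibrary", wavelengths = wl, spectra = sp)
}

#' @describeIn wavelengths wavelength grid of a component library
#' @export
setMethod("wavelengths", "ComponentLibrary", function(x) x@wavelengths)

setMethod("show", "ComponentLibrary", function(object) {
  cat(sprintf("ComponentLibrary: %d bands (%.0f-%.0f nm), components: %s\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths),
              paste(colnames(object@spectra), collapse = ", ")))
})
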