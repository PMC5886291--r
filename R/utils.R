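`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a local RNG seed, restoring global RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Otsu threshold on a numeric matrix (histogram-based, 256 bins).
otsuThreshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  u <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1L)), range = c(0, 1), levels = 256L)
  rng[1] + th * diff(rng)
}

# Flatten cube (lines x samples x bands) to a pixels x bands matrix for the
# pixel indices in `idx` (positions into the lines x samples plane).
pixelMatrix <- function(values, idx) {
  d <- dim(values)
  npl <- d[1] * d[2]
  out <- matrix(NA_real_, nrow = length(idx), ncol = d[3])
  for (b in seq_len(d[3])) out[, b] <- values[idx + (b - 1L) * npl]
  out
}

#' Convert an "as is" concentration to dry-weight basis
#'
#' Re-expresses a wet-basis concentration per unit dry mass:
#' \code{value / (1 - moisture)}.
#'
#' @param valueAsIs concentration on an "as is" (wet) basis, mg/g.
#' @param moistureFraction moisture mass fraction in [0, 1).
#' @return concentration on a dry-weight basis, mg/g.
#' @examples
#' toDryBasis(43.3, 0.094)  # ~ 47.8
#' @export
toDryBasis <- function(valueAsIs, moistureFraction) {
  if (any(moistureFraction < 0 | moistureFraction >= 1))
    stop("moisture fraction must lie in [0, 1)")
  valueAsIs / (1 - moistureFraction)
}
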