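# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Down-sized scene for fast tests; generator noise/concentration defaults
# are untouched.
testConfig <- function(...) {
  simulationConfig(lines = 64L, samples = 160L, ...)
}

# PLS1 beta via the Krylov-subspace characterization: the k-component PLS1
# solution is the least-squares solution restricted to the Krylov space
# span{s, (X'X)s, ..., (X'X)^(k-1) s} with s = X'y (X, y centred).
krylovPLSBeta <- function(X, y, k) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  G <- crossprod(Xc)
  s <- crossprod(Xc, yc)
  K <- matrix(0, ncol(X), k)
  v <- s
  for (j in seq_len(k)) { K[, j] <- v; v <- G %*% v }
  B <- qr.Q(qr(K))
  as.vector(B %*% solve(crossprod(B, G %*% B), crossprod(B, s)))
}

# Savitzky-Golay derivative by explicit per-window polynomial fit, with the
# same one-sided truncated-window edge policy.
polyfitSGOracle <- function(x, order, window, poly) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    t <- j - i
    fit <- lm(x[j] ~ stats::poly(t, degree = poly, raw = TRUE))
    cf <- coef(fit)
    out[i] <- if (order == 1L) cf[2] else 2 * cf[3]
  }
  out
}

# Per-band neighbourhood-mean oracle for bad-pixel replacement.
badPixelOracle <- function(values, coords) {
  d <- dim(values)
  flagged <- matrix(FALSE, d[2], d[3])
  flagged[coords] <- TRUE
  out <- values
  for (r in seq_len(nrow(coords))) {
    s <- coords[r, 1]; b <- coords[r, 2]
    for (l in seq_len(d[1])) {
      acc <- c()
      for (dl in -1:1) for (ds in -1:1) {
        if (dl == 0 && ds == 0) next
        l2 <- l + dl; s2 <- s + ds
        if (l2 < 1 || l2 > d[1] || s2 < 1 || s2 > d[2]) next
        if (flagged[s2, b]) next
        acc <- c(acc, values[l2, s2, b])
      }
      acc <- acc[!is.na(acc)]
      out[l, s, b] <- if (length(acc)) mean(acc) else NA_real_
    }
  }
  out
}

# Small raw scan with analytically known reflectance.
flatRawScan <- function(I, Ds, W, Dw, ts, tw, lines = 3L, samples = 4L, bands = 5L) {
  rawScan(array(I, c(lines, samples, bands)),
          matrix(W, samples, bands), matrix(Ds, samples, bands),
          matrix(Dw, samples, bands),
          exposureSample = ts, exposureWhite = tw,
          wavelengths = seq(1000, 1400, length.out = bands))
}

randomCube <- function(seed, lines = 6L, samples = 7L, bands = 8L, unit = "absorbance") {
  set.seed(seed)
  new("Hypercube",
      values = array(runif(lines * samples * bands, 0.2, 1), c(lines, samples, bands)),
      wavelengths = seq(1000, 2400, length.out = bands), unit = unit,
      metadata = list())
}
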