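test_that("full-rank PLS on noiseless linear data equals least squares", {
  set.seed(10)
  X <- matrix(rnorm(20 * 5), 20, 5)
  betaTrue <- c(1, -2, 0.5, 3, -1)
  y <- as.vector(X %*% betaTrue) + 4
  m <- fitPLS(X, y, nlv = 5L)
  expect_equal(coef(m), betaTrue, tolerance = 1e-8)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  cf <- coef(lm(y ~ X))
  expect_equal(coef(m), unname(cf[-1]), tolerance = 1e-8)
  expect_equal(m@intercept, unname(cf[1]), tolerance = 1e-8)
})

test_that("NIPALS beta matches the Krylov-subspace PLS oracle", {
  set.seed(11)
  for (k in 1:4) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    y <- rnorm(20)
    m <- fitPLS(X, y, nlv = k)
    expect_equal(coef(m), krylovPLSBeta(X, y, k), tolerance = 1e-6)
  }
})

test_that("NIPALS scores are orthogonal and both prediction routes agree", {
  set.seed(12)
  X <- matrix(rnorm(20 * 10), 20, 10)
  y <- rnorm(20)
  m <- fitPLS(X, y, nlv = 4L)
  # recompute scores by deflation to check the Gram matrix
  Xc <- scale(X, scale = FALSE)
  S <- matrix(0, 20, 4)
  for (k in 1:4) {
    S[, k] <- Xc %*% m@weights[, k]
    Xc <- Xc - S[, k] %*% t(m@xloadings[, k])
  }
  G <- crossprod(S)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(predict(m, X, route = "beta"), predict(m, X, route = "scores"),
               tolerance = 1e-8)
})

test_that("the zero-LV model predicts the response mean", {
  set.seed(13)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10, 7)
  m <- fitPLS(X, y, nlv = 0L)
  expect_equal(predict(m, X), rep(mean(y), 10), tolerance = 1e-12)
  expect_error(fitPLS(X, rep(1, 10), nlv = 1L), "variance")
})

test_that("model JSON round trip reproduces predictions exactly", {
  set.seed(14)
  X <- matrix(runif(15 * 12, 0.2, 1), 15, 12)
  y <- rnorm(15, 20, 3)
  m <- fitPLS(X, y, nlv = 3L, analyte = "caffeine",
              chain = preprocessChain("snv"))
  p <- file.path(withr::local_tempdir(), "model.json")
  writePLSModel(m, p)
  m2 <- readPLSModel(p)
  expect_identical(predict(m2, X), predict(m, X))
  expect_identical(m2@analyte, "caffeine")
})

test_that("error metrics follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3), tolerance = 1e-12)
  obs <- c(2, 4, 9)
  expect_equal(r2(rep(mean(obs), 3), obs), 0)
  expect_equal(rpd(2, 2), 1)
  expect_equal(errorPctRange(0, 1, 5), 0)
  expect_error(errorPctRange(1, 5, 5), "exceed")
})

test_that("cross-validation partitions, converges and is seed-reproducible", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n * 12), n, 12)
  y <- as.vector(X %*% rnorm(12)) + 10
  res <- crossValidate(X, y, maxLV = 12, nSegments = 20, seed = 9)
  expect_true(all(table(res$cv@segments) == 2))       # 40 objects, 20 segments
  expect_lt(res$cv@rmsecvCurve[12], 1e-6)             # noiseless linear data
  res2 <- crossValidate(X, y, maxLV = 12, nSegments = 20, seed = 9)
  expect_identical(res$cv@rmsecvCurve, res2$cv@rmsecvCurve)
  expect_identical(res$cv@segments, res2$cv@segments)
  expect_error(crossValidate(X[1:10, ], y[1:10], maxLV = 3, nSegments = 20),
               "leave-one-out")
})

test_that("calibration error never increases with more latent variables", {
  set.seed(16)
  X <- matrix(rnorm(30 * 15), 30, 15)
  y <- as.vector(X %*% rnorm(15)) + rnorm(30)
  res <- crossValidate(X, y, maxLV = 8, nSegments = 10, seed = 2)
  expect_true(all(diff(res$cv@rmsecCurve) <= 1e-10))
})

test_that("LV selection picks the most parsimonious near-minimum", {
  expect_equal(selectLV(c(5, 3, 2, 3, 4), tol = 0), 3L)
  expect_equal(selectLV(rep(2, 6)), 1L)
  expect_equal(selectLV(c(5, 3, 2.9, 2.88, 3.1), tol = 0.02), 3L)
})

test_that("band selection ranks |beta| with separation and wavelength ties", {
  beta <- rep(0.01, 50)
  beta[c(5, 15, 25, 35, 45)] <- c(5, 4, 3, 2, 1)
  m <- new("PLSModel", nlv = 1L, weights = matrix(0, 50, 1),
           xloadings = matrix(0, 50, 1), yloadings = 0,
           xcenter = rep(0, 50), ycenter = 0, beta = beta, intercept = 0,
           wavelengths = seq(1000, 2000, length.out = 50),
           chain = preprocessChain(), analyte = NA_character_, basis = "as_is")
  expect_equal(selectBands(m, 5), c(5L, 15L, 25L, 35L, 45L))
  expect_equal(selectBands(m, 50, minSep = 0L), 1:50)
  # tie: equal maxima -> lower wavelength first
  beta2 <- rep(0, 50); beta2[c(20, 40)] <- 3
  m@beta <- beta2
  expect_equal(selectBands(m, 1), 20L)
  # separation suppresses adjacent duplicates
  beta3 <- rep(0, 50); beta3[20:22] <- c(3, 2.9, 2.8); beta3[40] <- 1
  m@beta <- beta3
  expect_equal(selectBands(m, 2, minSep = 3L), c(20L, 40L))
})

test_that("refitting on informative bands keeps most of the model skill", {
  set.seed(17)
  n <- 60; nb <- 40
  X <- matrix(rnorm(n * nb, 0.5, 0.05), n, nb)
  signal <- c(4, 12, 20, 28, 36)
  conc <- runif(n, 10, 30)
  for (b in signal) X[, b] <- X[, b] + 0.01 * conc
  y <- conc
  full <- crossValidate(X, y, maxLV = 10, nSegments = 20, seed = 5)
  bands <- selectBands(full$model, 5, minSep = 3L)
  expect_true(all(vapply(bands, function(b) min(abs(b - signal)) <= 1, logical(1))))
  red <- refitReduced(X, y, bands = bands, maxLV = 10, nSegments = 20, seed = 5)
  expect_lte(red$model@nlv, 5L)
  expect_gt(red$cv@r2cv, full$cv@r2cv - 0.05)
  # reduced set = full set reproduces the full metrics
  same <- refitReduced(X, y, bands = 1:nb, maxLV = 10, nSegments = 20, seed = 5)
  expect_equal(same$cv@rmsecvCurve, full$cv@rmsecvCurve, tolerance = 1e-12)
})

test_that("spectral datasets align spectra, references and metadata", {
  set.seed(18)
  sp <- matrix(runif(6 * 10), 6, 10)
  conc <- data.frame(caffeine = rnorm(6, 18, 2), sucrose = rnorm(6, 43, 5))
  ds <- spectralDataset(sp, seq(1000, 1900, 100), conc,
                        species = rep(c("arabica", "robusta"), 3))
  expect_equal(spectraMatrix(ds), sp, ignore_attr = TRUE)
  expect_equal(referenceValues(ds, "caffeine"), conc$caffeine)
  expect_error(referenceValues(ds, "theobromine"), "theobromine")
  expect_error(spectralDataset(sp * NA, seq(1000, 1900, 100), conc), "missing")
})
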